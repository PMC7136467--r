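#include <Rcpp.h>
using namespace Rcpp;

// Maximal run-of-homozygosity windows on one chromosome of one individual.
//
// g: genotype calls ordered by position (0/1/2, -1 = missing);
// pos: base-pair positions (same order, ascending).
// A window [i, j] is valid when it has no heterozygote, at most
// allowed_missing missing calls, all adjacent gaps <= max_gap_bp,
// at least min_snps SNPs, span >= min_length_bp, and average density
// span / n_snps <= density_bp_per_snp. Reported windows are valid and
// maximal: neither one-SNP extension is valid.
// Returns a matrix with columns (start_idx, end_idx, n_snps, n_missing),
// indices 1-based.
// [[Rcpp::export]]
IntegerMatrix roh_scan_cpp(IntegerVector g, NumericVector pos,
                           int min_snps, double max_gap_bp,
                           double density_bp_per_snp, double min_length_bp,
                           int allowed_missing) {
  const int L = g.size();
  if (pos.size() != L) stop("genotype/position length mismatch");
  for (int i = 1; i < L; ++i)
    if (pos[i] < pos[i - 1]) stop("markers are not sorted by position");

  std::vector<int> starts, ends, nsnp, nmiss;

  // blocks bounded by heterozygous calls and oversized gaps: any valid
  // window lies entirely inside one block
  int b = 0;
  while (b < L) {
    if (g[b] == 1) { ++b; continue; }
    int e = b;
    while (e + 1 < L && g[e + 1] != 1 && pos[e + 1] - pos[e] <= max_gap_bp)
      ++e;

    // prefix missing counts within the block
    int B = e - b + 1;
    std::vector<int> miss(B + 1, 0);
    for (int t = 0; t < B; ++t)
      miss[t + 1] = miss[t] + (g[b + t] < 0 ? 1 : 0);

    auto missing_in = [&](int i, int j) {  // block-local inclusive
      return miss[j + 1] - miss[i];
    };
    auto dens_ok = [&](int i, int j) {     // block-local
      double span = pos[b + j] - pos[b + i];
      return span <= density_bp_per_snp * double(j - i + 1);
    };

    int J = 0;  // two-pointer upper bound (missing allowance), block-local
    for (int i = 0; i < B; ++i) {
      if (J < i) J = i;
      while (J + 1 < B && missing_in(i, J + 1) <= allowed_missing) ++J;
      for (int j = i + min_snps - 1; j <= J; ++j) {
        if (pos[b + j] - pos[b + i] < min_length_bp) continue;
        if (!dens_ok(i, j)) continue;
        // right extension: only the hard bound or density can fail
        bool right_valid = (j < J) && dens_ok(i, j + 1);
        if (right_valid) continue;
        // left extension: block start, missing allowance, or density
        bool left_valid = (i > 0) &&
          missing_in(i - 1, j) <= allowed_missing && dens_ok(i - 1, j);
        if (left_valid) continue;
        starts.push_back(b + i + 1);
        ends.push_back(b + j + 1);
        nsnp.push_back(j - i + 1);
        nmiss.push_back(missing_in(i, j));
      }
    }
    b = e + 1;
  }

  IntegerMatrix out(starts.size(), 4);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = ends[r];
    out(r, 2) = nsnp[r];
    out(r, 3) = nmiss[r];
  }
  colnames(out) = CharacterVector::create("start_idx", "end_idx",
                                          "n_snps", "n_missing");
  return out;
}
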