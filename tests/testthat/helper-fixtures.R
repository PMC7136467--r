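# Small deterministic fixtures shared across test files.

# A tiny dataset with known calls. Markers sit on one chromosome at 0.05 Mb
# spacing unless positions are given.
tiny_dataset <- function(calls, chrom = NULL, pos_bp = NULL,
                         populations = NULL, a1 = NULL, a2 = NULL) {
  L <- ncol(calls)
  n <- nrow(calls)
  if (is.null(chrom)) chrom <- rep(1L, L)
  if (is.null(pos_bp)) {
    pos_bp <- integer(L)
    for (chr in unique(chrom)) {
      k <- which(chrom == chr)
      pos_bp[k] <- seq(50000L, by = 50000L, length.out = length(k))
    }
  }
  if (is.null(a1)) a1 <- rep("A", L)
  if (is.null(a2)) a2 <- rep("G", L)
  if (is.null(populations)) populations <- rep("POP1", n)
  markers <- data.frame(id = sprintf("snp%03d", seq_len(L)),
                        chrom = as.integer(chrom),
                        pos_bp = as.integer(pos_bp),
                        a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("ind%03d", seq_len(n)),
                        population = populations, stringsAsFactors = FALSE)
  genotype_dataset(markers, samples, calls)
}

# Genotype matrix from per-population genotype count tables.
# counts: list of c(n_AA, n_Aa, n_aa) per population; calls count copies of A.
calls_from_counts <- function(counts) {
  rows <- lapply(counts, function(ct) rep(c(2L, 1L, 0L), times = ct))
  calls <- matrix(unlist(rows), nrow = sum(lengths(rows)), ncol = 1)
  pops <- rep(paste0("POP", seq_along(counts)), times = lengths(rows))
  list(calls = calls, populations = pops)
}

# Brute-force ROH oracle: enumerate all index windows and keep those that
# satisfy every rule, then filter to maximal ones (no valid one-SNP
# extension). Prefix counts make each window check O(1) so the full O(L^2)
# enumeration stays fast. g: vector in {0,1,2,NA}; pos in bp.
oracle_roh <- function(g, pos, min_snps = 15L, max_gap_mb = 1.0,
                       density_mb_per_snp = 0.1, min_length_mb = 4,
                       allowed_missing = 1L) {
  L <- length(g)
  pos <- as.numeric(pos)
  het_cum <- cumsum(!is.na(g) & g == 1L)
  mis_cum <- cumsum(is.na(g))
  big_gap <- c(FALSE, diff(pos) > max_gap_mb * 1e6)  # gap between k-1 and k
  gap_cum <- cumsum(big_gap)
  between <- function(cum, i, j) cum[j] - if (i > 1) cum[i - 1] else 0
  ok <- function(i, j) {
    if ((j - i + 1L) < min_snps) return(FALSE)
    if (between(het_cum, i, j) > 0) return(FALSE)
    if (between(mis_cum, i, j) > allowed_missing) return(FALSE)
    if (j > i && (gap_cum[j] - gap_cum[i]) > 0) return(FALSE)
    span <- pos[j] - pos[i]
    if (span < min_length_mb * 1e6) return(FALSE)
    if (span / (j - i + 1L) > density_mb_per_snp * 1e6) return(FALSE)
    TRUE
  }
  segs <- list()
  for (i in seq_len(L)) for (j in i:L) {
    if (!ok(i, j)) next
    left <- i > 1L && ok(i - 1L, j)
    right <- j < L && ok(i, j + 1L)
    if (!left && !right)
      segs[[length(segs) + 1L]] <- c(start_idx = i, end_idx = j)
  }
  if (!length(segs))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start_idx", "end_idx"))))
  unique(do.call(rbind, segs))
}

# Run the compiled ROH caller on a single genotype vector.
caller_roh <- function(g, pos, min_snps = 15L, max_gap_mb = 1.0,
                       density_mb_per_snp = 0.1, min_length_mb = 4,
                       allowed_missing = 1L) {
  calls <- matrix(as.integer(g), nrow = 1)
  ds <- tiny_dataset(calls, pos_bp = pos)
  p <- roh_params(min_snps = min_snps, max_gap_mb = max_gap_mb,
                  density_mb_per_snp = density_mb_per_snp,
                  classes = data.frame(min_length_mb = min_length_mb,
                                       allowed_missing = allowed_missing))
  seg <- detect_roh(ds, p, 1L)
  cbind(start_idx = match(seg$start_bp, pos),
        end_idx = match(seg$end_bp, pos))
}

# Independent scalar implementation of the Weir-Cockerham (1984) theta for
# one locus, written directly from the variance-component formulas.
oracle_wc_theta <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                             hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c, theta = a / (a + b + c))
}
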