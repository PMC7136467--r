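# helper: haplotype panel from a binary matrix (2 rows per individual),
# markers on one chromosome at 0.05 Mb spacing
hap_panel <- function(H, pos_bp = NULL, populations = NULL) {
  H <- as.matrix(H)
  L <- ncol(H); n <- nrow(H) / 2
  if (is.null(pos_bp)) pos_bp <- seq(50000L, by = 50000L, length.out = L)
  markers <- data.frame(id = sprintf("snp%03d", seq_len(L)), chrom = 1L,
                        pos_bp = as.integer(pos_bp),
                        a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  if (is.null(populations)) populations <- rep("POP1", n)
  samples <- data.frame(sample_id = sprintf("ind%03d", seq_len(n)),
                        population = populations, stringsAsFactors = FALSE)
  haplotype_panel(markers, H, samples,
                  chrom_lengths_mb = max(pos_bp) / 1e6 + 0.05)
}

test_that("grouped haplotype homozygosity matches hand counts", {
  expect_equal(hap_homozygosity(c(1L, 1L, 1L, 1L)), 1)
  expect_equal(hap_homozygosity(c(1L, 1L, 2L, 2L)), 2 / 6)  # 2*C(2,2)/C(4,2)
  expect_equal(hap_homozygosity(1:4), 0)
})

test_that("EHH is 1 everywhere for identical carrier haplotypes", {
  # 4 identical carrier haplotypes + 2 distinct non-carriers, 11 SNPs
  core <- 6L
  carrier <- rep(1L, 11)
  H <- rbind(carrier, carrier, carrier, carrier,
             rep(0L, 11), c(0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L))
  p <- hap_panel(H)
  e <- ehh(p, "snp006", allele = 1L)
  expect_true(all(e$left$ehh == 1))
  expect_true(all(e$right$ehh == 1))
  # iHH = full span both sides in Mb: 5 * 0.05 on each side
  expect_equal(e$ihh, 0.5, tolerance = 1e-12)
})

test_that("EHH drops to the split value when carriers diverge", {
  # 4 carriers split 2|2 immediately right of the core
  H <- matrix(0L, 8, 3)
  H[1:4, 2] <- 1L               # core at snp002, 4 carriers
  H[1:2, 3] <- 1L               # half the carriers diverge at snp003
  p <- hap_panel(H)
  e <- ehh(p, "snp002", allele = 1L)
  expect_equal(e$right$ehh, c(1, 2 / 6))
  expect_equal(e$left$ehh[2], 1)  # all carriers share allele 0 at snp001
})

test_that("EHH decay is monotone non-increasing outward", {
  set.seed(55)
  H <- matrix(rbinom(40 * 60, 1, 0.5), 40, 60)
  H[, 30] <- rep(c(1L, 0L), 20)
  p <- hap_panel(H)
  e <- ehh(p, "snp030", allele = 1L, floor = 0)
  expect_true(all(diff(e$left$ehh) <= 1e-12))
  expect_true(all(diff(e$right$ehh) <= 1e-12))
})

test_that("fewer than two carriers yields NA iHH, flagged not an error", {
  H <- matrix(0L, 4, 5)
  H[1, 3] <- 1L
  e <- ehh(hap_panel(H), "snp003", allele = 1L)
  expect_true(is.na(e$ihh))
  expect_equal(e$n_carriers, 1L)
})

test_that("iHS scan excludes low-MAF SNPs and standardizes to bins", {
  set.seed(56)
  H <- matrix(rbinom(40 * 300, 1, 0.5), 40, 300)
  H[, 5] <- c(1L, rep(0L, 39))   # MAF 0.025 < 0.05 -> excluded
  p <- hap_panel(H)
  res <- ihs_scan(p, scan_config())
  expect_false("snp005" %in% res$id)
  # per-bin means ~0 and sds ~1 by construction
  for (b in unique(res$bin)) {
    zb <- res$ihs[res$bin == b]
    if (length(zb) >= 2) {
      expect_lt(abs(mean(zb)), 1e-10)
      expect_lt(abs(sd(zb) - 1), 1e-10)
    }
  }
})

test_that("Rsb on identical panels is exactly zero", {
  set.seed(57)
  H <- matrix(rbinom(20 * 80, 1, 0.5), 20, 80)
  p <- hap_panel(H)
  res <- rsb_scan(p, p, scan_config())
  expect_true(all(res$unstandardized == 0))
  expect_true(all(res$rsb == 0))
  expect_true(all(!res$significant))
})

test_that("Rsb refuses mismatched marker maps", {
  set.seed(58)
  H <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  pa <- hap_panel(H)
  pb <- hap_panel(H, pos_bp = seq(60000L, by = 50000L, length.out = 30))
  expect_error(rsb_scan(pa, pb), "marker map")
})

test_that("eROHi fence flags exactly the planted high-incidence SNPs", {
  # 96 background values at 0.1 and four raised values: IQR = 0 so the
  # fence is Q3 = 0.1; exactly the four raised SNPs exceed it
  inc <- c(rep(0.1, 96), 0.5, 0.55, 0.6, 0.65)
  m <- data.frame(id = sprintf("snp%03d", 1:100), chrom = 1L,
                  pos_bp = seq(50000L, by = 50000L, length.out = 100))
  er <- erohi_outliers(inc, m, scan_config())
  expect_equal(er$outliers, sprintf("snp%03d", 97:100))
  expect_equal(nrow(er$islands), 1L)   # contiguous -> one island
  expect_equal(er$islands$n_snps, 4L)

  # uniform incidence: nothing flagged (strict inequality)
  er0 <- erohi_outliers(rep(0.3, 100), m, scan_config())
  expect_equal(length(er0$outliers), 0L)
  expect_equal(nrow(er0$islands), 0L)
})

test_that("fst_outliers returns the top loci against the pooled contrast", {
  set.seed(59)
  calls <- matrix(sample(0:2, 30 * 40, TRUE), nrow = 30)
  # plant one strongly differentiated locus
  calls[1:10, 7] <- 2L; calls[11:30, 7] <- 0L
  ds <- tiny_dataset(calls, populations = rep(c("LOCAL", "C1", "C2"),
                                              each = 10))
  out <- fst_outliers(ds, "LOCAL", c("C1", "C2"), top_n = 5)
  expect_equal(nrow(out), 5L)
  expect_equal(out$id[1], "snp007")
  expect_false(is.unsorted(rev(out$theta)))
})

test_that("overlap_report intersects sets and builds windows", {
  m <- data.frame(id = sprintf("snp%03d", 1:20), chrom = 1L,
                  pos_bp = seq(50000L, by = 50000L, length.out = 20))
  sets <- list(fst = c("snp003", "snp007", "snp010"),
               ihs = c("snp007", "snp010", "snp015"),
               rsb = c("snp010", "snp018"))
  ov <- overlap_report(sets, m, window_mb = 0.1)
  pw <- ov$pairwise
  expect_equal(pw$n_overlap[pw$set_a == "fst" & pw$set_b == "ihs"], 2L)
  expect_equal(ov$full, "snp010")
  w <- ov$windows[ov$windows$id == "snp007", ]
  # 0.1 Mb window at 0.35 Mb: [0.30, 0.40] contains snps 6, 7, 8 (inclusive)
  expect_equal(w$n_contained, 3L)
  expect_error(overlap_report(sets["fst"], m), "two")
})
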