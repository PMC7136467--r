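test_that("a clean homozygous stretch at chip density is one full run", {
  # 100 homozygous SNPs at 0.05 Mb spacing: span 4.95 Mb, density 0.0495
  # Mb/SNP -> a single >4Mb run covering all 100 SNPs
  pos <- seq(50000L, by = 50000L, length.out = 100L)
  g <- rep(2L, 100)
  seg <- caller_roh(g, pos)
  expect_equal(nrow(seg), 1L)
  expect_equal(unname(seg[1, ]), c(1L, 100L))
})

test_that("a stretch below the class length yields no run", {
  # 60 homozygous SNPs spanning 2.95 Mb < 4 Mb
  pos <- seq(50000L, by = 50000L, length.out = 60L)
  expect_equal(nrow(caller_roh(rep(0L, 60), pos)), 0L)
})

test_that("a gap above 1 Mb splits a run", {
  # two 100-SNP blocks separated by 1.2 Mb: two runs, not one
  pos <- c(seq(50000L, by = 50000L, length.out = 100L),
           seq(50000L + 99L * 50000L + 1200000L, by = 50000L,
               length.out = 100L))
  seg <- caller_roh(rep(2L, 200), pos)
  expect_equal(nrow(seg), 2L)
  expect_equal(unname(seg[, "end_idx"] - seg[, "start_idx"]), c(99L, 99L))
})

test_that("heterozygotes break runs, missing calls are budgeted", {
  pos <- seq(50000L, by = 50000L, length.out = 100L)
  g_het <- rep(2L, 100); g_het[50] <- 1L
  expect_equal(nrow(caller_roh(g_het, pos)), 0L)  # both halves < 4 Mb
  g_na1 <- rep(2L, 100); g_na1[50] <- NA
  seg <- caller_roh(g_na1, pos)                   # 1 missing allowed
  expect_equal(nrow(seg), 1L)
  g_na2 <- rep(2L, 100); g_na2[c(30, 60)] <- NA   # 2 missing: over budget
  seg2 <- caller_roh(g_na2, pos)
  expect_true(all(seg2[, "end_idx"] - seg2[, "start_idx"] < 99))
})

test_that("sparse SNPs fail the density rule", {
  # 20 homozygous SNPs at 0.5 Mb spacing: span 9.5 Mb but 0.5 Mb/SNP
  pos <- seq(500000L, by = 500000L, length.out = 20L)
  expect_equal(nrow(caller_roh(rep(2L, 20), pos)), 0L)
})

test_that("compiled caller agrees with the brute-force oracle", {
  # randomized small chromosomes covering hets, missing, gaps and density
  set.seed(1234)
  for (rep_i in 1:25) {
    L <- 120L
    gaps <- sample(c(40000L, 50000L, 60000L, 100000L, 1100000L), L - 1,
                   TRUE, prob = c(0.3, 0.3, 0.25, 0.1, 0.05))
    pos <- cumsum(c(50000L, gaps))
    g <- sample(c(0L, 2L, 1L, NA), L, TRUE, prob = c(0.45, 0.45, 0.05, 0.05))
    for (allowed in c(1L, 2L)) {
      got <- caller_roh(g, pos, allowed_missing = allowed)
      want <- oracle_roh(g, pos, allowed_missing = allowed)
      got <- got[order(got[, 1]), , drop = FALSE]
      want <- want[order(want[, 1]), , drop = FALSE]
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("class calls merge into bp unions", {
  segs <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2"),
    chrom = c(1L, 1L, 1L, 1L),
    start_bp = c(1000000L, 3000000L, 9000000L, 1000000L),
    end_bp   = c(5000000L, 7000000L, 12000000L, 2000000L),
    n_snps = 0L, n_missing = 0L, length_mb = 0, class_label = ">4Mb")
  un <- merge_class_calls(segs)
  u1 <- un[un$sample_id == "s1", ]
  expect_equal(u1$start_bp, c(1000000L, 9000000L))
  expect_equal(u1$end_bp, c(7000000L, 12000000L))
  expect_equal(u1$length_mb, c(6, 3))
  expect_equal(nrow(un[un$sample_id == "s2", ]), 1L)
})

test_that("froh arithmetic matches hand calculation", {
  un <- data.frame(sample_id = c("s1", "s1", "s2"),
                   chrom = 1L,
                   start_bp = c(0L, 0L, 0L),
                   end_bp = c(0L, 0L, 0L),
                   length_mb = c(5, 9, 244.45))
  # distinct rows per sample; only lengths matter for froh
  rec <- froh(un, roh_params(), sample_ids = c("s1", "s2", "s3"))
  expect_equal(rec$froh_gt4[1], 14 / 2444.5, tolerance = 1e-12)
  expect_equal(rec$froh_gt8[1], 9 / 2444.5, tolerance = 1e-12)
  expect_equal(rec$froh_4to8[1], 5 / 2444.5, tolerance = 1e-12)
  expect_equal(rec$froh_gt16[1], 0)
  expect_equal(rec$froh_gt4[2], 0.1, tolerance = 1e-12)
  expect_equal(unlist(rec[3, -1]), c(froh_gt4 = 0, froh_gt8 = 0,
                                     froh_4to8 = 0, froh_gt16 = 0))
})

test_that("froh classes are monotone on simulated data", {
  cfg <- sim_config(n_pops = 1, drift = 0.1, n_per_pop = 5, n_snps = 4000,
                    chrom_lengths_mb = c(120, 96),
                    roh_plan = roh_plan(target_fraction = 0.2), seed = 44)
  sim <- simulate_panel(cfg)
  params <- roh_params(genome_length_mb = 216)
  res <- call_roh(sim$dataset, params)
  rec <- res$inbreeding
  expect_true(all(rec$froh_gt4 >= rec$froh_gt8))
  expect_true(all(rec$froh_gt8 >= rec$froh_gt16))
  expect_true(all(rec$froh_4to8 >= 0))
  expect_gt(mean(rec$froh_gt4), 0.05)
})

test_that("roh incidence counts covering individuals per SNP", {
  calls <- matrix(1L, nrow = 4, ncol = 10)  # genotypes unused here
  ds <- tiny_dataset(calls)
  un <- data.frame(sample_id = c("ind001", "ind002"),
                   chrom = 1L,
                   start_bp = c(50000L, 150000L),
                   end_bp = c(200000L, 250000L),
                   length_mb = c(0.15, 0.1))
  inc <- roh_incidence(un, ds, "POP1")
  # SNPs at 0.05..0.50 Mb; covered counts: snp1 by ind1; snp2 (0.10) by
  # ind1; snp3 (0.15) by both; snp4 (0.20) by both; snp5 (0.25) by ind2
  expect_equal(unname(inc[1:6]), c(1, 1, 2, 2, 1, 0) / 4)
})
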