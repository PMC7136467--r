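test_that("population frequencies follow the drift model's moments", {
  set.seed(1)
  L <- 20000
  F_drift <- 0.2
  fr <- draw_population_freqs(L, K = 2, F_drift = F_drift, seed = 99)
  # Conditional moments: E[p_k | pbar] = pbar, Var[p_k | pbar] = F pbar(1-pbar)
  for (k in 1:2) {
    dev2 <- (fr$p[k, ] - fr$p_bar)^2
    ratio <- mean(dev2) / mean(F_drift * fr$p_bar * (1 - fr$p_bar))
    expect_lt(abs(ratio - 1), 0.10)
    expect_lt(abs(mean(fr$p[k, ] - fr$p_bar)), 0.01)
  }
  # ancestral frequencies uniform on (0.05, 0.95)
  expect_gte(min(fr$p_bar), 0.05)
  expect_lte(max(fr$p_bar), 0.95)
  expect_lt(abs(mean(fr$p_bar) - 0.5), 0.01)
})

test_that("zero drift collapses populations onto the ancestral frequency", {
  fr <- draw_population_freqs(500, K = 3, F_drift = 1e-8, seed = 4)
  expect_lt(max(abs(fr$p[1, ] - fr$p_bar)), 1e-3)
  expect_lt(max(abs(fr$p[2, ] - fr$p[3, ])), 2e-3)
})

test_that("simulate_panel is reproducible and haplotypes match calls", {
  cfg <- sim_config(n_pops = 2, drift = 0.2, n_per_pop = 5, n_snps = 300,
                    chrom_lengths_mb = c(60, 40), seed = 17)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$dataset$calls, s2$dataset$calls)
  expect_identical(s1$panel$haplotypes, s2$panel$haplotypes)
  # collapse identity: calls = hap(2i-1) + hap(2i)
  H <- s1$panel$haplotypes
  coll <- H[seq(1, nrow(H), 2), ] + H[seq(2, nrow(H), 2), ]
  expect_equal(unname(s1$dataset$calls), unname(coll))
  # marker map respects chromosome lengths
  m <- s1$dataset$markers
  expect_true(all(m$pos_bp[m$chrom == 1] <= 60e6))
  expect_true(all(m$pos_bp[m$chrom == 2] <= 40e6))
  expect_false(is.unsorted(m$pos_bp[m$chrom == 1]))
})

test_that("degenerate ancestry Q gives pure-population panels", {
  # one row per individual: first 20 pure cluster 1, next 20 pure cluster 2
  Q <- rbind(matrix(c(1, 0), 20, 2, byrow = TRUE),
             matrix(c(0, 1), 20, 2, byrow = TRUE))
  cfg <- sim_config(n_pops = 2, drift = 0.5, n_per_pop = 20, n_snps = 2000,
                    chrom_lengths_mb = 100, admixture_Q = Q, seed = 2)
  sim <- simulate_panel(cfg)
  # with strong drift the two pure populations differ in frequency
  f1 <- allele_freq(subset_populations(sim$dataset, "POP1"))
  f2 <- allele_freq(subset_populations(sim$dataset, "POP2"))
  expect_gt(mean(abs(f1 - f2)), 0.1)
  expect_equal(sim$truth$Q, Q, ignore_attr = TRUE)
})

test_that("autozygosity injection creates homozygous tracts of planned size", {
  cfg <- sim_config(n_pops = 1, drift = 0.1, n_per_pop = 4, n_snps = 4000,
                    chrom_lengths_mb = c(120, 96),
                    roh_plan = roh_plan(target_fraction = 0.15), seed = 8)
  sim <- simulate_panel(cfg)
  tr <- sim$truth$roh
  expect_true(all(tr$length_mb >= 4))
  # every planned tract is perfectly homozygous in the calls
  m <- sim$dataset$markers
  for (row in seq_len(nrow(tr))) {
    i <- match(tr$sample_id[row], sim$dataset$samples$sample_id)
    k <- which(m$chrom == tr$chrom[row] & m$pos_bp >= tr$start_bp[row] &
                 m$pos_bp <= tr$end_bp[row])
    expect_true(all(sim$dataset$calls[i, k] %in% c(0L, 2L)))
  }
  # per-individual planned fraction is close to the target
  glen <- sum(cfg$chrom_lengths_mb)
  frac <- tapply(tr$length_mb, tr$sample_id, sum) / glen
  expect_true(all(abs(frac - 0.15) < 0.08))
})

test_that("sweep injection fixes the focal allele in carriers", {
  cfg <- sim_config(n_pops = 2, drift = 0.2, n_per_pop = 10, n_snps = 1000,
                    chrom_lengths_mb = 100,
                    sweep_plan = sweep_plan("POP1", carrier_freq = 0.8,
                                            half_length_mb = 2), seed = 5)
  sim <- simulate_panel(cfg)
  tr <- sim$truth$sweep
  foc <- match(tr$focal_marker, sim$panel$markers$id)
  pa <- subset_panel_populations(sim$panel, "POP1")
  expect_equal(sum(pa$haplotypes[, foc] == 1), round(0.8 * nrow(pa$haplotypes)))
  # carriers share one haplotype across the core window
  core <- which(sim$panel$markers$chrom == tr$chrom &
                  abs(sim$panel$markers$pos_bp -
                        sim$panel$markers$pos_bp[foc]) <= 2e6)
  carriers <- which(pa$haplotypes[, foc] == 1)
  core_haps <- pa$haplotypes[carriers, core, drop = FALSE]
  expect_true(all(apply(core_haps, 2, function(col) length(unique(col)) == 1)))
})

test_that("missingness injection hits the requested rate", {
  cfg <- sim_config(n_pops = 1, drift = 0.1, n_per_pop = 10, n_snps = 5000,
                    chrom_lengths_mb = 100, missing_rate = 0.03, seed = 9)
  sim <- simulate_panel(cfg)
  rate <- mean(is.na(sim$dataset$calls))
  expect_lt(abs(rate - 0.03), 0.005)
})

test_that("stage_seed is deterministic and within integer range", {
  expect_identical(stage_seed(123, 5), stage_seed(123, 5))
  expect_false(stage_seed(123, 5) == stage_seed(123, 6))
  s <- vapply(1:50, function(o) stage_seed(2^30, o), numeric(1))
  expect_true(all(s >= 0 & s < 2^31))
})
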