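test_that("single-locus theta matches the independent hand-derived oracle", {
  # pop1 genotype counts (AA, Aa, aa) = (4, 4, 2); pop2 = (1, 4, 5).
  # Oracle value computed from the variance-component formulas by hand
  # (helper oracle_wc_theta) and frozen: theta = 28/243.
  ct <- calls_from_counts(list(c(4L, 4L, 2L), c(1L, 4L, 5L)))
  ds <- tiny_dataset(ct$calls, populations = ct$populations)
  res <- wc_fst(ds)
  oracle <- oracle_wc_theta(n_i = c(10, 10), p_i = c(0.6, 0.3),
                            h_i = c(0.4, 0.4))
  expect_equal(res$per_locus$theta, 28 / 243, tolerance = 1e-12)
  expect_equal(res$per_locus$theta, unname(oracle["theta"]),
               tolerance = 1e-12)
  expect_equal(res$per_locus$a, unname(oracle["a"]), tolerance = 1e-12)
  expect_equal(res$per_locus$b, unname(oracle["b"]), tolerance = 1e-12)
  expect_equal(res$per_locus$c, unname(oracle["c"]), tolerance = 1e-12)
  expect_equal(res$theta_multi, res$per_locus$theta, tolerance = 1e-12)
})

test_that("theta is near zero for identical populations and one at fixation", {
  ct <- calls_from_counts(list(c(3L, 4L, 3L), c(3L, 4L, 3L)))
  ds <- tiny_dataset(ct$calls, populations = ct$populations)
  th <- wc_fst(ds)$per_locus$theta
  expect_lte(th, 0)             # unbiased estimator undershoots at equality
  expect_lt(abs(th), 0.1)

  ct2 <- calls_from_counts(list(c(10L, 0L, 0L), c(0L, 0L, 10L)))
  ds2 <- tiny_dataset(ct2$calls, populations = ct2$populations)
  expect_equal(wc_fst(ds2)$per_locus$theta, 1.0, tolerance = 1e-12)
})

test_that("theta is invariant to allele swap and population order", {
  ct <- calls_from_counts(list(c(4L, 4L, 2L), c(1L, 4L, 5L)))
  ds <- tiny_dataset(ct$calls, populations = ct$populations)
  ds_sw <- tiny_dataset(2L - ct$calls, populations = ct$populations)
  expect_equal(wc_fst(ds_sw)$per_locus$theta, wc_fst(ds)$per_locus$theta,
               tolerance = 1e-12)
  expect_equal(wc_fst(ds, pops = c("POP2", "POP1"))$theta_multi,
               wc_fst(ds, pops = c("POP1", "POP2"))$theta_multi,
               tolerance = 1e-12)
})

test_that("multilocus theta is the ratio of summed components", {
  set.seed(30)
  calls <- matrix(sample(0:2, 20 * 50, TRUE), nrow = 20)
  ds <- tiny_dataset(calls, populations = rep(c("A", "B"), each = 10))
  res <- wc_fst(ds)
  pl <- res$per_locus[!is.na(res$per_locus$theta), ]
  expect_equal(res$theta_multi,
               sum(pl$a) / sum(pl$a + pl$b + pl$c), tolerance = 1e-12)
  # and NOT (in general) the mean of per-locus ratios
  expect_false(isTRUE(all.equal(res$theta_multi, mean(pl$theta),
                                tolerance = 1e-6)))
})

test_that("monomorphic loci are excluded and counted", {
  calls <- cbind(rep(2L, 8), c(rep(2L, 4), rep(0L, 4)))
  ds <- tiny_dataset(calls, populations = rep(c("A", "B"), each = 4))
  res <- wc_fst(ds)
  expect_equal(res$n_excluded, 1L)
  expect_true(is.na(res$per_locus$theta[1]))
  expect_equal(res$per_locus$theta[2], 1.0)
})

test_that("pooled populations act as one population", {
  ct <- calls_from_counts(list(c(4L, 4L, 2L), c(1L, 2L, 2L), c(0L, 2L, 3L)))
  ds <- tiny_dataset(ct$calls, populations = ct$populations)
  pooled <- wc_fst(ds, pops = c("POP1", "COM"),
                   pool = list(COM = c("POP2", "POP3")))
  ct2 <- calls_from_counts(list(c(4L, 4L, 2L), c(1L, 4L, 5L)))
  ds2 <- tiny_dataset(ct2$calls, populations = ct2$populations)
  expect_equal(pooled$theta_multi, wc_fst(ds2)$theta_multi, tolerance = 1e-12)
})

test_that("Reynolds distance transforms and clamps correctly", {
  M <- matrix(c(0, 0.25, 0.25, 0), 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))
  D <- reynolds_distance(M)
  expect_equal(D["A", "B"], -log(0.75), tolerance = 1e-12)
  Mneg <- M; Mneg[1, 2] <- Mneg[2, 1] <- -0.01
  expect_equal(reynolds_distance(Mneg)["A", "B"], 0)
  Mone <- M; Mone[1, 2] <- Mone[2, 1] <- 1
  expect_warning(Dc <- reynolds_distance(Mone, cap = 10), "capped")
  expect_equal(Dc["A", "B"], 10)
  expect_equal(attr(Dc, "n_capped"), 1L)
})

test_that("neighbor-joining recovers additive trees exactly", {
  # 4-taxon additive tree: ((A:1,B:2):1,(C:3,D:4)); internal edge 1
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d <- function(i, j, v) D[i, j] <<- D[j, i] <<- v
  d("A", "B", 3); d("A", "C", 5); d("A", "D", 6)
  d("B", "C", 6); d("B", "D", 7); d("C", "D", 7)
  tr <- nj_tree(D)
  path <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_lt(max(abs(path - D)), 1e-9)
  # NJ pairs the cherries correctly
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
})

test_that("nj_tree clamps small negative branches and keeps raw lengths", {
  set.seed(31)
  cfg <- sim_config(n_pops = 3, drift = 0.2, n_per_pop = 8, n_snps = 500,
                    chrom_lengths_mb = 100, seed = 31)
  sim <- simulate_panel(cfg)
  M <- pairwise_fst_matrix(sim$dataset)$matrix
  tr <- nj_tree(reynolds_distance(M))
  expect_true(all(tr$edge.length >= 0))
  expect_equal(length(attr(tr, "raw_edge_length")), length(tr$edge.length))
})
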