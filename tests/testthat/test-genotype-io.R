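test_that("genotype_dataset validates and sorts markers", {
  ds <- tiny_dataset(matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 2))
  expect_s3_class(ds, "GenotypeDataset")
  expect_equal(n_samples(ds), 2L)
  expect_equal(n_markers(ds), 3L)

  # unsorted positions get sorted, calls follow the permutation
  m <- data.frame(id = c("b", "a"), chrom = c(1L, 1L),
                  pos_bp = c(200L, 100L), a1 = "A", a2 = "G")
  s <- data.frame(sample_id = "i1", population = "P")
  ds2 <- genotype_dataset(m, s, matrix(c(2L, 0L), nrow = 1))
  expect_equal(ds2$markers$id, c("a", "b"))
  expect_equal(as.vector(ds2$calls), c(0L, 2L))

  expect_error(genotype_dataset(m, s, matrix(c(3L, 0L), nrow = 1)),
               "calls")
  m_dup <- m; m_dup$id <- c("a", "a")
  expect_error(genotype_dataset(m_dup, s, matrix(c(0L, 0L), nrow = 1)),
               "duplicate")
})

test_that("binary PLINK round trip preserves the dataset", {
  set.seed(42)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 5 * 20, TRUE), nrow = 5)
  ds <- tiny_dataset(calls, populations = c("A", "A", "B", "B", "B"))
  prefix <- file.path(tempdir(), "rt_bin")
  write_plink(ds, prefix, "binary")
  pops <- file.path(tempdir(), "rt_bin_pops.tsv")
  write_pop_table(ds, pops)
  ds2 <- read_plink(prefix, "binary", pop_table = pops)
  expect_equal(ds2$calls, ds$calls)
  expect_equal(ds2$markers$id, ds$markers$id)
  expect_equal(ds2$markers$pos_bp, ds$markers$pos_bp)
  expect_equal(ds2$samples$population, ds$samples$population)
})

test_that("bed decoding matches the 2-bit code table by hand", {
  # One sample, four markers with genotypes 2, 1, 0, NA (copies of A1).
  # SNP-major: one byte per marker; codes 00=2 copies, 10=1, 11=0, 01=NA.
  ds <- tiny_dataset(matrix(c(2L, 1L, 0L, NA), nrow = 1))
  prefix <- file.path(tempdir(), "hand_bed")
  write_plink(ds, prefix, "binary")
  raw <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  expect_identical(raw[4:7], as.raw(c(0x00, 0x02, 0x03, 0x01)))
  ds2 <- read_plink(prefix, "binary")
  expect_equal(as.vector(ds2$calls), c(2L, 1L, 0L, NA))
})

test_that("text PLINK round trip preserves calls via the A1 sidecar", {
  set.seed(7)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 4 * 12, TRUE,
                         prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 4)
  ds <- tiny_dataset(calls)
  prefix <- file.path(tempdir(), "rt_txt")
  write_plink(ds, prefix, "text")
  expect_true(file.exists(paste0(prefix, ".a1")))
  ds2 <- read_plink(prefix, "text")
  expect_equal(ds2$calls, ds$calls)
})

test_that("text reader defaults A1 to the minor allele", {
  # 3 samples at 1 locus: G/G, G/G, A/G -> A is minor, so calls count A.
  ped <- c("F1 s1 0 0 0 -9 G G",
           "F1 s2 0 0 0 -9 G G",
           "F1 s3 0 0 0 -9 A G")
  map <- "1 snp1 0 1000"
  prefix <- file.path(tempdir(), "minor")
  writeLines(ped, paste0(prefix, ".ped"))
  writeLines(map, paste0(prefix, ".map"))
  ds <- read_plink(prefix, "text")
  expect_equal(as.vector(ds$calls), c(0L, 0L, 1L))
  expect_equal(ds$markers$a1, "A")
})

test_that("SNP and sample QC apply thresholds with correct boundaries", {
  # 10 samples x 3 SNPs; SNP2 has 2/10 = 20% missing (> 10% -> removed),
  # SNP3 exactly 10% (kept).
  calls <- matrix(1L, nrow = 10, ncol = 3)
  calls[1:2, 2] <- NA
  calls[1, 3] <- NA
  ds <- tiny_dataset(calls)
  res <- apply_snp_qc(ds, max_snp_missing = 0.10)
  expect_equal(n_markers(res$dataset), 2L)
  expect_equal(res$report$removals$reason, "missingness")

  # score thresholds: GenCall exactly 0.7 removed (<=), above kept;
  # GenTrain exactly 0.4 removed
  ds2 <- tiny_dataset(matrix(1L, 4, 3))
  scores <- data.frame(id = ds2$markers$id,
                       gencall = c(0.70, 0.71, 0.9),
                       gentrain = c(0.9, 0.9, 0.40))
  res2 <- apply_snp_qc(ds2, max_snp_missing = 0.10, scores = scores)
  expect_equal(res2$dataset$markers$id, "snp002")

  # sample QC: exactly 5% missing is retained, above removed
  calls3 <- matrix(1L, nrow = 2, ncol = 20)
  calls3[1, 1] <- NA          # 5%  -> kept
  calls3[2, 1:2] <- NA        # 10% -> removed
  ds3 <- tiny_dataset(calls3)
  res3 <- apply_sample_qc(ds3, max_sample_missing = 0.05)
  expect_equal(res3$dataset$samples$sample_id, "ind001")
})

test_that("QC report counts balance and QC is idempotent", {
  set.seed(11)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 30 * 50, TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 30)
  ds <- tiny_dataset(calls)
  qc <- qc_pipeline(ds, max_snp_missing = 0.10, max_sample_missing = 0.05)
  rep_snp <- qc$reports$snp
  expect_equal(rep_snp$n_in, rep_snp$n_out + nrow(rep_snp$removals))
  qc2 <- qc_pipeline(qc$dataset, max_snp_missing = 0.10,
                     max_sample_missing = 0.05)
  expect_equal(qc2$dataset$calls, qc$dataset$calls)
  expect_equal(nrow(qc2$reports$snp$removals), 0L)
})

test_that("intersect_merge flips strands and drops conflicting loci", {
  # locus 1: same alleles -> kept; locus 2: strand-flipped (A/G vs T/C)
  # -> flipped and kept; locus 3: allele mismatch -> dropped.
  a <- tiny_dataset(matrix(c(2L, 1L, 0L), nrow = 1),
                    a1 = c("A", "A", "A"), a2 = c("G", "G", "G"))
  b <- tiny_dataset(matrix(c(0L, 2L, 2L), nrow = 1),
                    a1 = c("A", "T", "A"), a2 = c("G", "C", "C"))
  b$samples$sample_id <- "ind999"
  b$samples$population <- "POP2"
  merged <- intersect_merge(a, b)
  expect_equal(n_markers(merged), 2L)
  expect_equal(merged$markers$id, c("snp001", "snp002"))
  # flipped locus: b's T/C counts map directly onto A/G counts
  expect_equal(unname(merged$calls[, 2]), c(1L, 2L))
  log <- attr(merged, "merge_log")
  expect_equal(log$reason, "allele mismatch")
  expect_equal(log$id, "snp003")
  expect_error(intersect_merge(a, a), "sample")
})

test_that("thinning is deterministic, sorted and seed-sensitive", {
  set.seed(3)
  ds <- tiny_dataset(matrix(sample(0:2, 2 * 500, TRUE), nrow = 2))
  t1 <- thin_snps(ds, 100, seed = 5)
  t2 <- thin_snps(ds, 100, seed = 5)
  t3 <- thin_snps(ds, 100, seed = 6)
  expect_equal(n_markers(t1), 100L)
  expect_identical(t1$markers$id, t2$markers$id)
  expect_false(identical(t1$markers$id, t3$markers$id))
  expect_false(is.unsorted(t1$markers$pos_bp))
})
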