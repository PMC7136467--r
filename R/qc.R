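#' SNP-level quality control
#'
#' Removes, in this order: markers off the mapped autosomes (chromosome
#' outside 1-18 or position <= 0); markers whose missing-call fraction
#' exceeds `max_snp_missing`; and, when a score table is supplied, markers
#' with GenCall score <= `gencall_min` or GenTrain score <= `gentrain_min`
#' (both boundaries inclusive on the removal side, as on the chip QC this
#' mirrors).
#'
#' @param ds a [genotype_dataset()]
#' @param max_snp_missing maximum tolerated per-SNP missing fraction
#'   (removal when strictly greater); default 0.10
#' @param gencall_min GenCall removal boundary (removed when `<=`); default 0.7
#' @param gentrain_min GenTrain removal boundary (removed when `<=`); default 0.4
#' @param scores optional data.frame with columns `id` and one or both of
#'   `gencall`, `gentrain`. When `NULL` only missingness/autosome rules apply.
#' @param n_autosomes autosome count of the map (default 18)
#' @return list with elements `dataset` (filtered) and `report` (a `QcReport`:
#'   counts in/out per axis and a removal table with reasons)
#' @export
apply_snp_qc <- function(ds, max_snp_missing = 0.10,
                         gencall_min = 0.7, gentrain_min = 0.4,
                         scores = NULL, n_autosomes = 18L) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1)
  removed <- character(0); reason <- character(0)
  flag <- function(ids, why) {
    removed <<- c(removed, ids)
    reason <<- c(reason, rep(why, length(ids)))
  }
  m <- ds$markers
  bad_chr <- m$chrom < 1L | m$chrom > n_autosomes
  flag(m$id[bad_chr], "non-autosomal")
  bad_pos <- !bad_chr & (is.na(m$pos_bp) | m$pos_bp <= 0L)
  flag(m$id[bad_pos], "unmapped")
  keep <- !(bad_chr | bad_pos)
  miss_frac <- colMeans(is.na(ds$calls))
  bad_miss <- keep & miss_frac > max_snp_missing
  flag(m$id[bad_miss], "missingness")
  keep <- keep & !bad_miss
  scores_used <- !is.null(scores)
  if (scores_used) {
    idx <- match(m$id, scores$id)
    if (!is.null(scores$gencall)) {
      gc <- scores$gencall[idx]
      bad_gc <- keep & !is.na(gc) & gc <= gencall_min
      flag(m$id[bad_gc], "gencall")
      keep <- keep & !bad_gc
    }
    if (!is.null(scores$gentrain)) {
      gt <- scores$gentrain[idx]
      bad_gt <- keep & !is.na(gt) & gt <= gentrain_min
      flag(m$id[bad_gt], "gentrain")
      keep <- keep & !bad_gt
    }
  }
  if (!any(keep)) stop("empty panel: all SNPs removed by QC")
  out <- subset_dataset(ds, marker_idx = which(keep))
  report <- qc_report(axis = "snp",
                      n_in = n_markers(ds), n_out = n_markers(out),
                      removed = removed, reason = reason,
                      notes = if (scores_used) character(0) else
                        "quality scores unavailable; score rules not applied")
  list(dataset = out, report = report)
}

#' Sample-level quality control
#'
#' Removes samples whose missing-call fraction strictly exceeds
#' `max_sample_missing` (default 5%). A population losing all its members is
#' recorded as a warning note in the report, not an error.
#'
#' @param ds a [genotype_dataset()]
#' @param max_sample_missing maximum tolerated per-sample missing fraction
#' @return list with `dataset` and `report`, as [apply_snp_qc()]
#' @export
apply_sample_qc <- function(ds, max_sample_missing = 0.05) {
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1)
  miss_frac <- rowMeans(is.na(ds$calls))
  bad <- miss_frac > max_sample_missing
  notes <- character(0)
  if (any(bad)) {
    lost <- setdiff(unique(ds$samples$population),
                    unique(ds$samples$population[!bad]))
    if (length(lost))
      notes <- sprintf("population %s lost all members", lost)
  }
  if (all(bad)) stop("empty panel: all samples removed by QC")
  out <- subset_dataset(ds, sample_idx = which(!bad))
  report <- qc_report(axis = "sample",
                      n_in = n_samples(ds), n_out = n_samples(out),
                      removed = ds$samples$sample_id[bad],
                      reason = rep("missingness", sum(bad)),
                      notes = notes)
  list(dataset = out, report = report)
}

qc_report <- function(axis, n_in, n_out, removed, reason, notes = character(0)) {
  stopifnot(n_in == n_out + length(removed))
  structure(list(axis = axis, n_in = n_in, n_out = n_out,
                 removals = data.frame(id = removed, reason = reason,
                                       stringsAsFactors = FALSE),
                 notes = notes),
            class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QC [%s]: %d in, %d out, %d removed\n",
              x$axis, x$n_in, x$n_out, nrow(x$removals)))
  if (nrow(x$removals)) print(table(x$removals$reason))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `QcReport`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_qc_report <- function(report, path) {
  hdr <- sprintf("# axis=%s n_in=%d n_out=%d", report$axis,
                 report$n_in, report$n_out)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (n in report$notes) writeLines(paste("# note:", n), con)
  utils::write.table(report$removals, con, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Full chip QC sequence
#'
#' Autosome filter and SNP rules, then sample missingness, then one SNP
#' missingness re-check (sample removal can only lower per-SNP missingness,
#' so a single re-check restores idempotence).
#'
#' @inheritParams apply_snp_qc
#' @inheritParams apply_sample_qc
#' @return list with `dataset` and `reports` (list of `QcReport`)
#' @export
qc_pipeline <- function(ds, max_snp_missing = 0.10, max_sample_missing = 0.05,
                        gencall_min = 0.7, gentrain_min = 0.4, scores = NULL) {
  s1 <- apply_snp_qc(ds, max_snp_missing, gencall_min, gentrain_min, scores)
  s2 <- apply_sample_qc(s1$dataset, max_sample_missing)
  s3 <- apply_snp_qc(s2$dataset, max_snp_missing, gencall_min, gentrain_min,
                     scores)
  list(dataset = s3$dataset, reports = list(snp = s1$report,
                                            sample = s2$report,
                                            snp_recheck = s3$report))
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Merge two panels on their shared markers
#'
#' Markers are intersected by id (requiring identical chromosome and
#' position); samples are concatenated. Allele coding of `b` is harmonized to
#' `a`: direct allele-pair match, else strand flip for unambiguous pairs
#' (complementing both alleles), else the marker is dropped. A/T and C/G
#' (strand-ambiguous) markers are kept only when the allele pairs match
#' directly and the counted-allele frequencies agree to within
#' `ambiguous_freq_tol`; otherwise they are dropped with the reason logged.
#'
#' @param a,b [genotype_dataset()] objects with disjoint sample ids
#' @param ambiguous_freq_tol frequency-agreement tolerance for A/T / C/G
#'   markers (default 0.2)
#' @return a merged [genotype_dataset()] with attribute `"merge_log"`
#'   (data.frame of dropped markers and reasons)
#' @export
intersect_merge <- function(a, b, ambiguous_freq_tol = 0.2) {
  if (length(intersect(a$samples$sample_id, b$samples$sample_id)))
    stop("datasets share sample ids")
  common <- intersect(a$markers$id, b$markers$id)
  if (length(common) == 0) stop("empty panel: no shared markers")
  ia <- match(common, a$markers$id); ib <- match(common, b$markers$id)
  ma <- a$markers[ia, ]; mb <- b$markers[ib, ]
  same_pos <- ma$chrom == mb$chrom & ma$pos_bp == mb$pos_bp
  freq_a <- allele_freq(a)[ia]; freq_b <- allele_freq(b)[ib]
  drop_reason <- rep(NA_character_, length(common))
  flip_strand <- swap_alleles <- rep(FALSE, length(common))
  for (k in seq_along(common)) {
    if (!same_pos[k]) { drop_reason[k] <- "position mismatch"; next }
    pa <- c(ma$a1[k], ma$a2[k]); pb <- c(mb$a1[k], mb$a2[k])
    ambiguous <- all(sort(pa) == sort(unname(COMPLEMENT[pa])))
    if (ambiguous) {
      if (!setequal(pa, pb)) { drop_reason[k] <- "ambiguous alleles"; next }
      fb <- if (pb[1] == pa[1]) freq_b[k] else 1 - freq_b[k]
      if (is.na(freq_a[k]) || is.na(fb) ||
          abs(freq_a[k] - fb) > ambiguous_freq_tol) {
        drop_reason[k] <- "ambiguous frequency mismatch"; next
      }
      swap_alleles[k] <- pb[1] != pa[1]
    } else if (setequal(pa, pb)) {
      swap_alleles[k] <- pb[1] != pa[1]
    } else if (setequal(pa, unname(COMPLEMENT[pb]))) {
      flip_strand[k] <- TRUE
      swap_alleles[k] <- unname(COMPLEMENT[pb[1]]) != pa[1]
    } else {
      drop_reason[k] <- "allele mismatch"
    }
  }
  keep <- is.na(drop_reason)
  if (!any(keep)) stop("empty panel: no markers survive harmonization")
  calls_b <- b$calls[, ib[keep], drop = FALSE]
  sw <- swap_alleles[keep]
  calls_b[, sw] <- 2L - calls_b[, sw]
  merged <- genotype_dataset(
    ma[keep, , drop = FALSE],
    rbind(a$samples, b$samples),
    rbind(a$calls[, ia[keep], drop = FALSE], calls_b))
  attr(merged, "merge_log") <- data.frame(
    id = common[!keep], reason = drop_reason[!keep], stringsAsFactors = FALSE)
  merged
}

#' Thin a panel to a target marker count
#'
#' Uniform random subsample without replacement, map order preserved;
#' reproducible for a given seed. Used to cut panels to a size tractable for
#' the admixture sampler.
#'
#' @param ds a [genotype_dataset()]
#' @param target_n number of markers to keep (default 15000)
#' @param seed integer RNG seed
#' @return a [genotype_dataset()]
#' @export
thin_snps <- function(ds, target_n = 15000L, seed) {
  L <- n_markers(ds)
  if (target_n > L) stop("target_n (", target_n, ") exceeds marker count (", L, ")")
  if (target_n == L) return(ds)
  keep <- with_seed(seed, sort(sample.int(L, target_n)))
  subset_dataset(ds, marker_idx = keep)
}
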