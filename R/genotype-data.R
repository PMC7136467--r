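#' Construct a genotype dataset
#'
#' The central container of the package: a diploid biallelic SNP panel with a
#' marker map and per-sample population labels. Genotype calls count copies of
#' the A1 allele of each marker (0, 1 or 2); missing calls are `NA`.
#'
#' @param markers data.frame with columns `id`, `chrom` (integer autosome,
#'   expected 1-18), `pos_bp` (integer, 1-based), `a1`, `a2` (allele symbols;
#'   calls count `a1`). Must be unique in `id`.
#' @param samples data.frame with columns `sample_id`, `population` and
#'   optionally `sex` (coded as in PLINK: 1 male, 2 female, 0 unknown).
#' @param calls integer matrix, `nrow(samples)` x `nrow(markers)`, entries in
#'   `{0, 1, 2, NA}`.
#' @param sort_markers sort markers by (chrom, pos_bp)? Default `TRUE`.
#'
#' @return An object of class `GenotypeDataset`: a list with elements
#'   `markers`, `samples`, `calls` (rows named by sample id, columns by
#'   marker id).
#' @export
genotype_dataset <- function(markers, samples, calls, sort_markers = TRUE) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_m <- c("id", "chrom", "pos_bp", "a1", "a2")
  if (!all(need_m %in% names(markers)))
    stop("markers must have columns: ", paste(need_m, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(samples)))
    stop("samples must have columns sample_id, population")
  if (is.null(samples$sex)) samples$sex <- 0L
  if (anyDuplicated(markers$id))
    stop("duplicate marker ids")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers))
    stop("calls matrix dimensions do not match samples x markers")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("calls must be 0, 1, 2 or NA")
  markers$chrom <- as.integer(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)
  if (sort_markers) {
    o <- order(markers$chrom, markers$pos_bp)
    markers <- markers[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, markers$id)
  structure(list(markers = markers, samples = samples, calls = calls),
            class = "GenotypeDataset")
}

#' @export
print.GenotypeDataset <- function(x, ...) {
  cat(sprintf("GenotypeDataset: %d samples x %d SNPs\n",
              nrow(x$samples), nrow(x$markers)))
  cat(sprintf("  chromosomes: %s\n",
              paste(sort(unique(x$markers$chrom)), collapse = " ")))
  tab <- table(x$samples$population)
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s(%d)", names(tab), tab), collapse = " ")))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / markers
#' @param ds a `GenotypeDataset`
#' @return integer count
#' @export
n_samples <- function(ds) nrow(ds$samples)

#' @rdname n_samples
#' @export
n_markers <- function(ds) nrow(ds$markers)

#' Subset a dataset by samples or markers
#'
#' @param ds a `GenotypeDataset`
#' @param sample_idx logical/integer index or character sample ids
#' @param marker_idx logical/integer index or character marker ids
#' @return a `GenotypeDataset`
#' @export
subset_dataset <- function(ds, sample_idx = NULL, marker_idx = NULL) {
  si <- if (is.null(sample_idx)) seq_len(n_samples(ds)) else sample_idx
  mi <- if (is.null(marker_idx)) seq_len(n_markers(ds)) else marker_idx
  if (is.character(si)) si <- match(si, ds$samples$sample_id)
  if (is.character(mi)) mi <- match(mi, ds$markers$id)
  genotype_dataset(ds$markers[mi, , drop = FALSE],
                   ds$samples[si, , drop = FALSE],
                   ds$calls[si, mi, drop = FALSE],
                   sort_markers = FALSE)
}

#' Subset a dataset to the given populations
#' @param ds a `GenotypeDataset`
#' @param pops character vector of population labels
#' @return a `GenotypeDataset`
#' @export
subset_populations <- function(ds, pops) {
  keep <- ds$samples$population %in% pops
  if (!any(keep)) stop("no samples in populations: ", paste(pops, collapse = ", "))
  subset_dataset(ds, sample_idx = which(keep))
}

#' Allele frequency of the counted (A1) allele per marker
#' @param ds a `GenotypeDataset`
#' @return numeric vector, length `n_markers(ds)`; NaN where fully missing
#' @export
allele_freq <- function(ds) {
  colMeans(ds$calls, na.rm = TRUE) / 2
}
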