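#' Pairwise identity-by-state coancestry
#'
#' For each pair of individuals, the mean over mutually non-missing loci of
#' `1 - |g_i - g_j| / 2`, i.e. the proportion of alleles shared identical by
#' state. The companion `counts` matrix records how many loci entered each
#' pair's mean; pairs with no shared loci are `NA`.
#'
#' @param ds a [genotype_dataset()]
#' @return a `CoancestryMatrix`: list with `values` (n x n symmetric, unit
#'   diagonal), `counts`, and `labels`
#' @export
ibs_matrix <- function(ds) {
  if (n_samples(ds) < 2) stop("IBS needs at least two samples")
  g <- ds$calls
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  storage.mode(g0) <- "double"
  obs <- obs * 1
  counts <- obs %*% t(obs)
  # sum |gi - gj| = sum gi^2 + gj^2 - 2 gi gj over shared loci, g in {0,1,2}:
  # |gi-gj| in {0,1,2}; |gi-gj| = gi+gj-2*min -> use squared trick instead:
  # |gi-gj|^2 in {0,1,4}; cannot recover |.| from squares alone, so compute
  # via the three indicator matrices of g = 0,1,2.
  I0 <- (g0 == 0 & obs == 1) * 1
  I1 <- (g0 == 1 & obs == 1) * 1
  I2 <- (g0 == 2 & obs == 1) * 1
  # |gi-gj| totals: pairs (0,1) and (1,2) differ by 1; (0,2) by 2
  d1 <- I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1)
  d2 <- I0 %*% t(I2) + I2 %*% t(I0)
  diff_sum <- d1 + 2 * d2
  vals <- 1 - diff_sum / (2 * counts)
  vals[counts == 0] <- NA_real_
  vals <- (vals + t(vals)) / 2    # remove floating asymmetry
  diag(vals)[rowSums(obs) > 0] <- 1
  dimnames(vals) <- dimnames(counts) <-
    list(ds$samples$sample_id, ds$samples$sample_id)
  structure(list(values = vals, counts = counts,
                 labels = ds$samples$sample_id),
            class = "CoancestryMatrix")
}

#' @export
print.CoancestryMatrix <- function(x, ...) {
  cat(sprintf("CoancestryMatrix: %d samples, mean off-diagonal IBS %.4f\n",
              length(x$labels),
              mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' Classical multidimensional scaling of IBS coancestry
#'
#' Transforms the coancestry matrix to the distance `D = 1 - IBS` and applies
#' Torgerson scaling (double-centering of `-D^2/2` and eigendecomposition;
#' coordinates are the top-`d` eigenvectors scaled by the square root of
#' their eigenvalues). Eigenvector signs are fixed by forcing each axis's
#' largest-magnitude loading positive, so plots are reproducible. Negative
#' eigenvalues beyond `d` are reported, not used.
#'
#' @param coancestry a `CoancestryMatrix` from [ibs_matrix()], or a plain
#'   distance matrix when `is_distance = TRUE`
#' @param d number of dimensions (default 2)
#' @param is_distance treat `coancestry` as an already-formed distance matrix
#' @return an `MdsResult`: list with `coordinates` (n x d, centroid at the
#'   origin), `eigenvalues` (all n, non-increasing), `d`, `labels`
#' @export
classical_mds <- function(coancestry, d = 2L, is_distance = FALSE) {
  if (is_distance) {
    D <- as.matrix(coancestry)
    labels <- rownames(D)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  } else {
    stopifnot(inherits(coancestry, "CoancestryMatrix"))
    if (anyNA(coancestry$values))
      stop("coancestry has missing cells; remove samples with no shared loci")
    D <- 1 - coancestry$values
    labels <- coancestry$labels
  }
  if (anyNA(D)) stop("distance matrix has missing cells")
  k <- min(d, nrow(D) - 1L)
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < d)   # axes beyond the positive spectrum are degenerate
    coords <- cbind(coords, matrix(0, nrow(coords), d - ncol(coords)))
  # sign convention: largest-|loading| entry positive on each axis
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- labels
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 d = d, labels = labels),
            class = "MdsResult")
}

#' @export
print.MdsResult <- function(x, ...) {
  ev <- x$eigenvalues[seq_len(min(4, length(x$eigenvalues)))]
  cat(sprintf("MdsResult: %d points in %d dimensions; leading eigenvalues %s\n",
              nrow(x$coordinates), x$d,
              paste(signif(ev, 4), collapse = ", ")))
  invisible(x)
}

#' Write MDS coordinates as TSV
#' @param mds an `MdsResult`
#' @param ds optional [genotype_dataset()] supplying population labels
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mds <- function(mds, path, ds = NULL) {
  df <- data.frame(sample_id = mds$labels, mds$coordinates)
  names(df)[-1] <- paste0("C", seq_len(ncol(mds$coordinates)))
  if (!is.null(ds))
    df$population <- ds$samples$population[match(df$sample_id,
                                                 ds$samples$sample_id)]
  write_tsv(df, path)
}
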