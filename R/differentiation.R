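#' Weir-Cockerham F_ST variance components
#'
#' Computes, per locus, the among-population (`a`), among-individual-within-
#' population (`b`) and within-individual (`c`) variance components of Weir &
#' Cockerham's estimator from sample sizes, allele frequencies, and observed
#' heterozygosities, plus `theta = a / (a + b + c)`. The multilocus estimator
#' is the ratio of sums `sum(a) / sum(a + b + c)` (the recommended
#' combination), not the mean of per-locus ratios. A locus contributes only
#' when at least two populations have two or more genotyped individuals
#' there; loci monomorphic across all populations (zero total variance) are
#' excluded from the sums and counted.
#'
#' @param ds a [genotype_dataset()]
#' @param pops population labels to include (default: all in `ds`)
#' @param pool optional named list mapping new pooled labels to vectors of
#'   original labels, e.g. `list(COMMERCIAL = c("LDR1","PIT1"))`
#' @return an `FstResult`: list with `per_locus` (data.frame id, chrom,
#'   pos_bp, a, b, c, theta), `theta_multi`, `n_excluded`, `pops`
#' @export
wc_fst <- function(ds, pops = NULL, pool = NULL) {
  labels <- ds$samples$population
  if (!is.null(pool)) {
    for (nm in names(pool)) labels[labels %in% pool[[nm]]] <- nm
  }
  if (is.null(pops)) pops <- unique(labels)
  if (length(pops) < 2) stop("F_ST needs at least two populations")
  g <- ds$calls[labels %in% pops, , drop = FALSE]
  labels <- labels[labels %in% pops]
  L <- ncol(g)
  r_tot <- length(pops)
  n_i <- p_i <- h_i <- matrix(0, r_tot, L)
  for (k in seq_len(r_tot)) {
    gk <- g[labels == pops[k], , drop = FALSE]
    obs <- !is.na(gk)
    n_i[k, ] <- colSums(obs)
    p_i[k, ] <- colSums(gk, na.rm = TRUE) / (2 * pmax(n_i[k, ], 1))
    h_i[k, ] <- colSums(gk == 1L, na.rm = TRUE) / pmax(n_i[k, ], 1)
  }
  use <- n_i >= 2                      # population contributes at a locus
  n_i[!use] <- 0; p_i[!use] <- 0; h_i[!use] <- 0
  r <- colSums(use)
  ok <- r >= 2
  nbar <- colSums(n_i) / pmax(r, 1)
  sum_n2 <- colSums(n_i^2)
  n_c <- (colSums(n_i) - sum_n2 / pmax(colSums(n_i), 1)) / pmax(r - 1, 1)
  pbar <- colSums(n_i * p_i) / pmax(colSums(n_i), 1)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r_tot))^2) /
    (pmax(r - 1, 1) * pmax(nbar, 1))
  hbar <- colSums(n_i * h_i) / pmax(colSums(n_i), 1)
  a <- (nbar / n_c) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  defined <- ok & is.finite(denom) & abs(denom) > 1e-14
  a[!defined] <- NA; b[!defined] <- NA; cc[!defined] <- NA
  theta <- a / denom
  theta[!defined] <- NA
  per_locus <- data.frame(id = ds$markers$id, chrom = ds$markers$chrom,
                          pos_bp = ds$markers$pos_bp,
                          a = a, b = b, c = cc, theta = theta,
                          stringsAsFactors = FALSE)
  theta_multi <- sum(a[defined]) / sum(denom[defined])
  structure(list(per_locus = per_locus, theta_multi = theta_multi,
                 n_excluded = sum(!defined), pops = pops),
            class = "FstResult")
}

#' @export
print.FstResult <- function(x, ...) {
  cat(sprintf("FstResult [%s]: multilocus theta = %.4f (%d loci excluded)\n",
              paste(x$pops, collapse = " vs "), x$theta_multi, x$n_excluded))
  invisible(x)
}

#' Pairwise multilocus F_ST matrix
#'
#' Multilocus Weir-Cockerham theta for every unordered population pair, plus
#' each population's mean off-diagonal theta and the grand mean over pairs.
#' Populations with fewer than two members are excluded with a warning.
#'
#' @param ds a [genotype_dataset()]
#' @param pops population labels (default: all)
#' @return list with `matrix` (a `DistanceMatrix`-style labeled symmetric
#'   matrix, zero diagonal), `pop_mean` (named vector), `grand_mean`
#' @export
pairwise_fst_matrix <- function(ds, pops = NULL) {
  if (is.null(pops)) pops <- unique(ds$samples$population)
  sizes <- table(ds$samples$population)[pops]
  small <- pops[is.na(sizes) | sizes < 2]
  if (length(small)) {
    warning("excluding populations with <2 members: ",
            paste(small, collapse = ", "))
    pops <- setdiff(pops, small)
  }
  if (length(pops) < 2) stop("need at least two usable populations")
  K <- length(pops)
  M <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    th <- wc_fst(ds, pops = c(pops[i], pops[j]))$theta_multi
    M[i, j] <- M[j, i] <- th
  }
  pop_mean <- vapply(seq_len(K), function(i) mean(M[i, -i]), numeric(1))
  names(pop_mean) <- pops
  list(matrix = M, pop_mean = pop_mean,
       grand_mean = mean(M[upper.tri(M)]))
}

#' Reynolds genetic distance
#'
#' Elementwise `D = -ln(1 - theta)` on a pairwise F_ST matrix. Negative theta
#' (estimator noise) maps to distance 0; theta at or above 1 is set to `cap`.
#' The number of clamped entries is recorded in attributes.
#'
#' @param theta_matrix symmetric matrix of pairwise multilocus theta
#' @param cap distance assigned where `theta >= 1` (default 10)
#' @return labeled symmetric distance matrix with attributes `n_clamped`,
#'   `n_capped`
#' @export
reynolds_distance <- function(theta_matrix, cap = 10) {
  th <- as.matrix(theta_matrix)
  D <- -log(1 - pmin(pmax(th, 0), 1 - 1e-12))
  n_clamped <- sum(th[upper.tri(th)] < 0)
  over <- th >= 1
  if (any(over[upper.tri(over)])) {
    warning(sum(over[upper.tri(over)]), " pairs with theta >= 1 capped")
    D[over] <- cap
  }
  diag(D) <- 0
  attr(D, "n_clamped") <- n_clamped
  attr(D, "n_capped") <- sum(over[upper.tri(over)])
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`) on a complete symmetric distance
#' matrix, returning an unrooted `phylo` tree. Negative branch lengths are
#' clamped to zero; the raw lengths are retained in
#' `attr(tree, "raw_edge_length")`.
#'
#' @param D labeled symmetric distance matrix (>= 3 taxa)
#' @return an `ape` `phylo` object
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("NJ needs at least three taxa")
  if (anyNA(D)) stop("distance matrix has missing cells")
  tree <- ape::nj(D)
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "raw_edge_length") <- raw
  tree
}

#' Write a tree as Newick
#' @param tree a `phylo` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write per-locus F_ST as TSV
#' @param fst an `FstResult`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fst <- function(fst, path) {
  write_tsv(fst$per_locus, path)
}
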