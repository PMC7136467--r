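#' Admixture model specification
#'
#' Settings for the Gibbs sampler of the admixture model with correlated
#' allele frequencies: each individual has ancestry proportions over K
#' clusters; each allele copy originates from a cluster, whose allele
#' frequencies are tied to ancestral frequencies through per-cluster drift
#' parameters (the F-model). Production defaults follow common practice for
#' SNP panels (10,000 burn-in + 100,000 repetitions, 20 independent runs);
#' analyses in this package's tests and examples use much shorter chains.
#'
#' @param K number of clusters (>= 1)
#' @param burn_in burn-in sweeps
#' @param reps post-burn-in sweeps
#' @param n_runs independent chains for [admixture_runs()]
#' @param alpha initial Dirichlet admixture parameter (updated by
#'   Metropolis steps with sd `alpha_step`, uniform prior on (0, alpha_max])
#' @param lambda Beta parameter of the ancestral-frequency prior (fixed)
#' @param alpha_max upper bound of the alpha prior
#' @param alpha_step Metropolis step sd for alpha
#' @param f_step Metropolis step sd for the drift parameters
#' @param pbar_step Metropolis step sd for ancestral frequencies
#' @param seed integer RNG seed
#' @return an `AdmixtureModelSpec` list
#' @export
admixture_spec <- function(K, burn_in = 10000L, reps = 100000L, n_runs = 20L,
                           alpha = 1.0, lambda = 1.0, alpha_max = 10,
                           alpha_step = 0.025, f_step = 0.01,
                           pbar_step = 0.05, seed = 1L) {
  stopifnot(K >= 1, burn_in > 0, reps > 0, n_runs >= 1)
  structure(list(K = as.integer(K), burn_in = as.integer(burn_in),
                 reps = as.integer(reps), n_runs = as.integer(n_runs),
                 alpha = alpha, lambda = lambda, alpha_max = alpha_max,
                 alpha_step = alpha_step, f_step = f_step,
                 pbar_step = pbar_step, seed = as.integer(seed)),
            class = "AdmixtureModelSpec")
}

#' Fit the admixture model by Gibbs sampling
#'
#' One chain of the correlated-allele-frequency admixture sampler. Sweep
#' order: ancestry assignment of every allele copy given (Q, P); Q rows from
#' their Dirichlet posterior; cluster frequencies P from their Beta posterior
#' under the drift-tied prior; ancestral frequencies, drift parameters and
#' alpha by random-walk Metropolis. Missing genotypes contribute no
#' likelihood. Posterior means are taken over post-burn-in sweeps.
#'
#' @param ds a [genotype_dataset()]
#' @param spec an [admixture_spec()]
#' @return an `AdmixtureFit`: list with `Q` (n x K posterior-mean ancestry,
#'   rows summing to 1), `P` (K x L), `F_k`, `alpha`, `lnl_trace` (all
#'   sweeps), `ln_evidence`, `spec`
#' @export
fit_admixture <- function(ds, spec) {
  stopifnot(inherits(spec, "AdmixtureModelSpec"))
  if (spec$K > n_samples(ds)) stop("K exceeds the number of individuals")
  G <- ds$calls
  G[is.na(G)] <- -1L
  fit <- with_seed(spec$seed,
                   admixture_gibbs_cpp(G, spec$K, spec$burn_in, spec$reps,
                                       spec$alpha, spec$lambda,
                                       spec$alpha_max, spec$alpha_step,
                                       spec$f_step, spec$pbar_step))
  rownames(fit$Q) <- ds$samples$sample_id
  post <- fit$lnl_trace[(spec$burn_in + 1):length(fit$lnl_trace)]
  structure(list(Q = fit$Q, P = fit$P, F_k = fit$F_k, alpha = fit$alpha,
                 lnl_trace = fit$lnl_trace,
                 ln_evidence = ln_evidence(post), spec = spec),
            class = "AdmixtureFit")
}

#' @export
print.AdmixtureFit <- function(x, ...) {
  cat(sprintf("AdmixtureFit: K = %d, n = %d, ln Pr(X|K) = %.1f\n",
              x$spec$K, nrow(x$Q), x$ln_evidence))
  cat(sprintf("  drift F_k: %s; alpha = %.3f\n",
              paste(signif(x$F_k, 3), collapse = ", "), x$alpha))
  invisible(x)
}

#' Model evidence from a log-likelihood trace
#'
#' The harmonic-style estimator of `ln Pr(X|K)` used for choosing K:
#' `mean(lnL) - var(lnL) / 2` over the post-burn-in trace, with the sample
#' (n-1) variance.
#'
#' @param trace numeric vector of post-burn-in data log-likelihoods
#' @return scalar estimate of ln Pr(X|K)
#' @export
ln_evidence <- function(trace) {
  if (length(trace) < 2) stop("trace needs at least 2 sweeps")
  mean(trace) - stats::var(trace) / 2
}

#' Rate-of-change statistic for the number of clusters
#'
#' The Evanno-style second-difference statistic:
#' `Delta K = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`, where
#' the mean and sd are over independent runs at each K. Endpoints are
#' undefined (`NA`); a zero sd yields `Inf`, flagged rather than an error.
#'
#' @param evidence data.frame with columns `K` and `ln_evidence`, one row per
#'   run (>= 2 runs for >= 3 consecutive K values)
#' @return data.frame with columns `K`, `mean_ln`, `sd_ln`, `delta_k`
#' @export
delta_k <- function(evidence) {
  agg <- do.call(rbind, lapply(split(evidence, evidence$K), function(d) {
    data.frame(K = d$K[1], mean_ln = mean(d$ln_evidence),
               sd_ln = stats::sd(d$ln_evidence),
               n_runs = nrow(d))
  }))
  agg <- agg[order(agg$K), ]
  if (nrow(agg) < 3) stop("delta K needs at least 3 consecutive K values")
  if (any(diff(agg$K) != 1)) stop("K values must be consecutive")
  if (any(agg$n_runs < 2)) stop("delta K needs >= 2 runs per K")
  dk <- rep(NA_real_, nrow(agg))
  for (i in 2:(nrow(agg) - 1)) {
    num <- abs(agg$mean_ln[i + 1] - 2 * agg$mean_ln[i] + agg$mean_ln[i - 1])
    dk[i] <- if (agg$sd_ln[i] == 0) Inf else num / agg$sd_ln[i]
  }
  agg$delta_k <- dk
  agg[c("K", "mean_ln", "sd_ln", "delta_k")]
}

#' Align independent admixture runs
#'
#' Resolves label switching across runs: the first run is the reference, and
#' each subsequent run's cluster columns are permuted greedily to minimize
#' the total absolute difference to the incrementally built mean. Returns the
#' permutations, the aligned average Q, and each run's mean absolute distance
#' to the final average.
#'
#' @param runs list of n x K ancestry matrices (identical shapes)
#' @return an `AlignedRuns` list: `permutations`, `Q_mean`, `dispersion`,
#'   `aligned` (list of permuted Q matrices)
#' @export
align_runs <- function(runs) {
  if (!length(runs)) stop("no runs supplied")
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("runs have mismatched shapes")
  K <- ncol(runs[[1]])
  perms <- vector("list", length(runs))
  perms[[1]] <- seq_len(K)
  aligned <- list(runs[[1]])
  ref_sum <- runs[[1]]
  for (r in seq_along(runs)[-1]) {
    ref <- ref_sum / length(aligned)
    # greedy assignment: repeatedly take the (run column, ref column) pair
    # with the smallest absolute difference
    cost <- matrix(0, K, K)
    for (a in seq_len(K)) for (b in seq_len(K))
      cost[a, b] <- sum(abs(runs[[r]][, a] - ref[, b]))
    perm <- integer(K)
    free_a <- free_b <- rep(TRUE, K)
    for (step in seq_len(K)) {
      sub <- cost
      sub[!free_a, ] <- Inf; sub[, !free_b] <- Inf
      ij <- arrayInd(which.min(sub), dim(sub))
      perm[ij[2]] <- ij[1]
      free_a[ij[1]] <- FALSE; free_b[ij[2]] <- FALSE
    }
    perms[[r]] <- perm
    aligned[[r]] <- runs[[r]][, perm, drop = FALSE]
    ref_sum <- ref_sum + aligned[[r]]
  }
  Q_mean <- ref_sum / length(runs)
  dispersion <- vapply(aligned, function(q) mean(abs(q - Q_mean)), numeric(1))
  structure(list(permutations = perms, Q_mean = Q_mean,
                 dispersion = dispersion, aligned = aligned),
            class = "AlignedRuns")
}

#' Independent admixture runs at one K
#'
#' Runs `spec$n_runs` chains with distinct seeds derived from `spec$seed`,
#' aligns them, and returns the fits plus the aligned average ancestry.
#'
#' @param ds a [genotype_dataset()]
#' @param spec an [admixture_spec()]
#' @return list with `fits`, `aligned` (an `AlignedRuns`), `ln_evidence`
#'   (per-run vector)
#' @export
admixture_runs <- function(ds, spec) {
  fits <- lapply(seq_len(spec$n_runs), function(r) {
    s <- spec
    s$seed <- stage_seed(spec$seed, 100 + r)
    fit_admixture(ds, s)
  })
  aligned <- align_runs(lapply(fits, `[[`, "Q"))
  rownames(aligned$Q_mean) <- ds$samples$sample_id
  list(fits = fits, aligned = aligned,
       ln_evidence = vapply(fits, `[[`, numeric(1), "ln_evidence"))
}

#' Sweep K and pick the most likely number of clusters
#'
#' Fits `n_runs` chains at each K in `k_range`, reporting per-K evidence, the
#' Delta-K table (when the range allows), and the K maximizing the mean
#' evidence.
#'
#' @param ds a [genotype_dataset()]
#' @param k_range integer vector of K values
#' @param spec_template an [admixture_spec()] whose K is overridden
#' @return list with `evidence` (data.frame K, run, ln_evidence), `delta_k`
#'   (or NULL), `best_k`
#' @export
admixture_k_sweep <- function(ds, k_range, spec_template) {
  ev <- list()
  for (K in k_range) {
    for (r in seq_len(spec_template$n_runs)) {
      s <- spec_template
      s$K <- as.integer(K)
      s$seed <- stage_seed(spec_template$seed, 1000 * K + r)
      fit <- fit_admixture(ds, s)
      ev[[length(ev) + 1L]] <- data.frame(K = K, run = r,
                                          ln_evidence = fit$ln_evidence)
    }
  }
  ev <- do.call(rbind, ev)
  mean_ev <- tapply(ev$ln_evidence, ev$K, mean)
  dk <- if (length(k_range) >= 3 && spec_template$n_runs >= 2 &&
            all(diff(sort(k_range)) == 1)) delta_k(ev) else NULL
  list(evidence = ev, delta_k = dk,
       best_k = as.integer(names(which.max(mean_ev))))
}

#' Write ancestry proportions as TSV
#' @param Q ancestry matrix (rows named by sample)
#' @param ds optional [genotype_dataset()] supplying population labels
#' @param path output path
#' @return `path`, invisibly
#' @export
write_q_matrix <- function(Q, path, ds = NULL) {
  df <- data.frame(sample_id = rownames(Q), as.data.frame(unname(Q)))
  names(df)[-1] <- paste0("Q", seq_len(ncol(Q)))
  if (!is.null(ds))
    df <- cbind(df[1],
                population = ds$samples$population[
                  match(df$sample_id, ds$samples$sample_id)],
                df[-1])
  write_tsv(df, path)
}
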