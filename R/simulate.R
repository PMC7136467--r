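#' Autosome map of the simulated genome
#'
#' Eighteen autosome lengths (Mb) in realistic pig-like proportions, scaled to
#' sum to `total_mb` (default 2,444.5 Mb, the chip-covered autosomal genome
#' length used for all F_ROH denominators).
#'
#' @param total_mb total autosomal length in Mb
#' @return numeric vector of 18 chromosome lengths (Mb)
#' @export
default_chrom_lengths_mb <- function(total_mb = 2444.5) {
  raw <- c(315.3, 162.6, 144.8, 143.5, 111.5, 157.8, 134.8, 148.5, 153.7,
           79.1, 87.7, 63.6, 218.6, 153.9, 157.7, 86.9, 69.7, 61.2)
  raw / sum(raw) * total_mb
}

#' Simulation configuration
#'
#' Defines a multi-population Balding-Nichols panel: `K_true` populations with
#' per-population drift `F`, optional admixed ancestry rows, optional
#' autozygosity and sweep plans. Defaults emulate a 60K-chip study design:
#' 45,000 SNPs over 18 autosomes totalling 2,444.5 Mb and 16-20 individuals
#' per population.
#'
#' @param n_pops number of source populations (K_true)
#' @param drift per-population drift F_k in (0,1), recycled to `n_pops`
#' @param n_per_pop individuals per population, recycled to `n_pops`
#' @param n_snps total marker count
#' @param chrom_lengths_mb 18 chromosome lengths in Mb
#' @param pop_names population labels (default POP1..POPK)
#' @param admixture_Q optional matrix (sum(n_per_pop) x n_pops) of ancestry
#'   proportions, rows summing to 1; default: each individual 100% its own
#'   population
#' @param roh_plan optional plan from [roh_plan()]
#' @param sweep_plan optional plan from [sweep_plan()]
#' @param missing_rate uniform genotype missingness rate (default 0)
#' @param seed integer RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_pops = 2L, drift = 0.2, n_per_pop = 20L,
                       n_snps = 45000L,
                       chrom_lengths_mb = default_chrom_lengths_mb(),
                       pop_names = NULL, admixture_Q = NULL,
                       roh_plan = NULL, sweep_plan = NULL,
                       missing_rate = 0, seed = 1L) {
  drift <- rep_len(drift, n_pops)
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  if (any(drift <= 0 | drift >= 1)) stop("drift F_k must lie in (0,1)")
  if (any(chrom_lengths_mb <= 0)) stop("chromosome lengths must be positive")
  if (is.null(pop_names)) pop_names <- paste0("POP", seq_len(n_pops))
  n <- sum(n_per_pop)
  if (is.null(admixture_Q)) {
    admixture_Q <- matrix(0, n, n_pops)
    admixture_Q[cbind(seq_len(n), rep(seq_len(n_pops), n_per_pop))] <- 1
  } else {
    admixture_Q <- as.matrix(admixture_Q)
    if (nrow(admixture_Q) != n || ncol(admixture_Q) != n_pops)
      stop("admixture_Q must be ", n, " x ", n_pops)
    if (any(abs(rowSums(admixture_Q) - 1) > 1e-9))
      stop("admixture_Q rows must sum to 1")
  }
  structure(list(n_pops = n_pops, drift = drift, n_per_pop = n_per_pop,
                 n_snps = as.integer(n_snps),
                 chrom_lengths_mb = chrom_lengths_mb, pop_names = pop_names,
                 admixture_Q = admixture_Q, roh_plan = roh_plan,
                 sweep_plan = sweep_plan, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Autozygosity injection plan
#'
#' @param target_fraction per-individual target autozygous genome fraction in
#'   `[0,1)`; scalar or one value per individual
#' @param short_range,long_range segment-length ranges in Mb; segments are
#'   drawn from a 50/50 mixture of Uniform(short) and Uniform(long), giving
#'   both "remote" (4-8 Mb) and "recent" (>8 Mb) autozygosity
#' @param p_short mixture weight of the short class
#' @return a `roh_plan` list
#' @export
roh_plan <- function(target_fraction, short_range = c(4, 8),
                     long_range = c(8, 30), p_short = 0.5) {
  if (any(target_fraction < 0 | target_fraction >= 1))
    stop("target autozygous fraction must lie in [0,1)")
  structure(list(target_fraction = target_fraction, short_range = short_range,
                 long_range = long_range, p_short = p_short),
            class = "roh_plan")
}

#' Selective-sweep injection plan
#'
#' @param population label of the population carrying the sweep
#' @param focal_marker marker id of the focal SNP (or `NULL`: the marker
#'   nearest the midpoint of `chrom`)
#' @param chrom chromosome used when `focal_marker` is `NULL`
#' @param carrier_freq fraction of the population's haplotypes carrying the
#'   core haplotype
#' @param half_length_mb half-width of the shared core around the focus (Mb)
#' @return a `sweep_plan` list
#' @export
sweep_plan <- function(population, focal_marker = NULL, chrom = 1L,
                       carrier_freq = 0.8, half_length_mb = 2) {
  if (carrier_freq < 0 || carrier_freq > 1)
    stop("carrier_freq must lie in [0,1]")
  structure(list(population = population, focal_marker = focal_marker,
                 chrom = as.integer(chrom), carrier_freq = carrier_freq,
                 half_length_mb = half_length_mb),
            class = "sweep_plan")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws ancestral frequencies uniformly on `[0.05, 0.95]` and per-population
#' frequencies from the Balding-Nichols beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, independently over loci and populations,
#' so that `E[p_k] = p` and `Var[p_k] = F p (1-p)`.
#'
#' @param L locus count
#' @param K population count
#' @param F_drift per-population drift in (0,1), recycled to `K`
#' @param seed integer RNG seed
#' @return list with `p_bar` (length `L`) and `p` (`K x L`)
#' @export
draw_population_freqs <- function(L, K, F_drift, seed) {
  F_drift <- rep_len(F_drift, K)
  if (any(F_drift <= 0 | F_drift >= 1)) stop("drift F_k must lie in (0,1)")
  with_seed(seed, {
    p_bar <- stats::runif(L, 0.05, 0.95)
    p <- matrix(0, K, L)
    for (k in seq_len(K)) {
      Fk <- F_drift[k]
      p[k, ] <- stats::rbeta(L, p_bar * (1 - Fk) / Fk,
                             (1 - p_bar) * (1 - Fk) / Fk)
    }
    list(p_bar = p_bar, p = p)
  })
}

place_markers <- function(n_snps, chrom_lengths_mb) {
  n_chr <- length(chrom_lengths_mb)
  counts <- floor(n_snps * chrom_lengths_mb / sum(chrom_lengths_mb))
  short <- n_snps - sum(counts)
  if (short > 0) {
    extra <- order(chrom_lengths_mb, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  chrom <- rep(seq_len(n_chr), counts)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    sort(sample.int(floor(chrom_lengths_mb[c] * 1e6), counts[c]))
  }))
  data.frame(id = sprintf("snp_%d_%d", chrom, pos),
             chrom = as.integer(chrom), pos_bp = as.integer(pos),
             a1 = "A", a2 = "G", stringsAsFactors = FALSE)
}

#' Simulate a multi-population genotype and haplotype panel
#'
#' Each haplotype allele at each locus is drawn Bernoulli(`p[z, l]`), where
#' the copy's ancestry `z` is drawn from the individual's ancestry row;
#' markers are placed uniformly along the chromosomes. Calls count the A1
#' ("A") allele; the two haplotype rows of an individual sum exactly to its
#' genotype (before any missingness, which is applied to the genotype matrix
#' only).
#'
#' @param cfg a [sim_config()]
#' @return list with `dataset` (a [genotype_dataset()]), `panel`
#'   (a `HaplotypePanel`) and `truth` (list: Q, drift, p_bar, p, plus any
#'   injected ROH segments / sweep record)
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_pops; L <- cfg$n_snps; n <- sum(cfg$n_per_pop)
  freqs <- draw_population_freqs(L, K, cfg$drift, stage_seed(cfg$seed, 1))
  out <- with_seed(stage_seed(cfg$seed, 2), {
    markers <- place_markers(L, cfg$chrom_lengths_mb)
    hap <- matrix(0L, 2L * n, L)
    for (i in seq_len(n)) {
      q <- cfg$admixture_Q[i, ]
      for (copy in 1:2) {
        z <- sample.int(K, L, replace = TRUE, prob = q)
        hap[2L * (i - 1L) + copy, ] <-
          as.integer(stats::runif(L) < freqs$p[cbind(z, seq_len(L))])
      }
    }
    list(markers = markers, hap = hap)
  })
  pop <- rep(cfg$pop_names, cfg$n_per_pop)
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", pop,
                        unlist(lapply(cfg$n_per_pop, seq_len))),
    population = pop, sex = 0L, stringsAsFactors = FALSE)
  panel <- haplotype_panel(out$markers, out$hap, samples,
                           cfg$chrom_lengths_mb)
  truth <- list(Q = cfg$admixture_Q, drift = cfg$drift,
                p_bar = freqs$p_bar, p = freqs$p)
  if (!is.null(cfg$roh_plan)) {
    inj <- inject_autozygosity(panel, cfg$roh_plan, stage_seed(cfg$seed, 3))
    panel <- inj$panel
    truth$roh_segments <- inj$truth
  }
  if (!is.null(cfg$sweep_plan)) {
    inj <- inject_sweep(panel, cfg$sweep_plan, stage_seed(cfg$seed, 4))
    panel <- inj$panel
    truth$sweep <- inj$truth
  }
  calls <- haplotypes_to_calls(panel)
  if (cfg$missing_rate > 0) {
    calls <- with_seed(stage_seed(cfg$seed, 5), {
      calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
      calls
    })
  }
  ds <- genotype_dataset(panel$markers, samples, calls, sort_markers = FALSE)
  attr(ds, "chrom_lengths_mb") <- cfg$chrom_lengths_mb
  list(dataset = ds, panel = panel, truth = truth)
}

#' Construct a phased haplotype panel
#'
#' @param markers marker data.frame as in [genotype_dataset()]
#' @param haplotypes binary matrix, `2 * nrow(samples)` rows (two consecutive
#'   rows per individual) by `nrow(markers)` columns
#' @param samples sample data.frame as in [genotype_dataset()]
#' @param chrom_lengths_mb chromosome lengths backing the marker map
#' @return a `HaplotypePanel`
#' @export
haplotype_panel <- function(markers, haplotypes, samples,
                            chrom_lengths_mb = default_chrom_lengths_mb()) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * nrow(samples))
    stop("haplotype panel needs exactly two rows per individual")
  if (ncol(haplotypes) != nrow(markers))
    stop("haplotype columns must match marker count")
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotypes must be binary")
  structure(list(markers = as.data.frame(markers),
                 haplotypes = haplotypes,
                 samples = as.data.frame(samples),
                 chrom_lengths_mb = chrom_lengths_mb),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d haplotypes (%d individuals) x %d SNPs\n",
              nrow(x$haplotypes), nrow(x$samples), nrow(x$markers)))
  invisible(x)
}

#' Collapse haplotype pairs to genotype calls
#' @param panel a `HaplotypePanel`
#' @return integer matrix (individuals x markers) of A1-allele counts
#' @export
haplotypes_to_calls <- function(panel) {
  n <- nrow(panel$samples)
  g <- panel$haplotypes[2L * seq_len(n) - 1L, , drop = FALSE] +
    panel$haplotypes[2L * seq_len(n), , drop = FALSE]
  rownames(g) <- panel$samples$sample_id
  colnames(g) <- panel$markers$id
  g
}

#' Subset a haplotype panel to given populations
#' @param panel a `HaplotypePanel`
#' @param pops population labels to keep
#' @return a `HaplotypePanel`
#' @export
subset_panel_populations <- function(panel, pops) {
  keep <- which(panel$samples$population %in% pops)
  if (!length(keep)) stop("no samples in populations: ", paste(pops, collapse = ", "))
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haplotype_panel(panel$markers, panel$haplotypes[rows, , drop = FALSE],
                  panel$samples[keep, , drop = FALSE], panel$chrom_lengths_mb)
}

#' Inject autozygous segments into a haplotype panel
#'
#' For each individual, non-overlapping segments are drawn from the plan's
#' length mixture and placed uniformly (chromosome chosen proportional to
#' length) until the cumulative segment length reaches the individual's target
#' fraction of the genome; within each segment the first haplotype is copied
#' onto the second, making every contained SNP homozygous. Exact bp bounds are
#' recorded as truth.
#'
#' @param panel a `HaplotypePanel`
#' @param plan a [roh_plan()]
#' @param seed integer RNG seed
#' @return list with `panel` (modified) and `truth` (data.frame sample_id,
#'   chrom, start_bp, end_bp, length_mb)
#' @export
inject_autozygosity <- function(panel, plan, seed) {
  stopifnot(inherits(plan, "roh_plan"))
  n <- nrow(panel$samples)
  target <- rep_len(plan$target_fraction, n)
  genome_mb <- sum(panel$chrom_lengths_mb)
  with_seed(seed, {
    truth <- list()
    hap <- panel$haplotypes
    for (i in seq_len(n)) {
      if (target[i] <= 0) next
      placed <- data.frame(chrom = integer(0), start = numeric(0),
                           end = numeric(0))
      total_mb <- 0; tries <- 0
      while (total_mb < target[i] * genome_mb) {
        tries <- tries + 1
        if (tries > 10000)
          stop(sprintf(
            "autozygosity target unreachable for individual %d: %.1f Mb short",
            i, target[i] * genome_mb - total_mb))
        len <- if (stats::runif(1) < plan$p_short)
          stats::runif(1, plan$short_range[1], plan$short_range[2])
        else
          stats::runif(1, plan$long_range[1], plan$long_range[2])
        chr <- sample.int(length(panel$chrom_lengths_mb), 1,
                          prob = panel$chrom_lengths_mb)
        if (len >= panel$chrom_lengths_mb[chr]) next
        start <- stats::runif(1, 0, panel$chrom_lengths_mb[chr] - len)
        end <- start + len
        ours <- placed[placed$chrom == chr, ]
        if (nrow(ours) && any(start < ours$end & end > ours$start)) next
        placed <- rbind(placed, data.frame(chrom = chr, start = start,
                                           end = end))
        total_mb <- total_mb + len
        idx <- which(panel$markers$chrom == chr &
                       panel$markers$pos_bp >= start * 1e6 &
                       panel$markers$pos_bp <= end * 1e6)
        if (length(idx))
          hap[2L * i, idx] <- hap[2L * i - 1L, idx]
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = panel$samples$sample_id[i], chrom = chr,
          start_bp = as.integer(ceiling(start * 1e6)),
          end_bp = as.integer(floor(end * 1e6)),
          length_mb = len, stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(0), chrom = integer(0),
                 start_bp = integer(0), end_bp = integer(0),
                 length_mb = numeric(0))
    panel$haplotypes <- hap
    list(panel = panel, truth = truth)
  })
}

#' Inject a selective sweep into a haplotype panel
#'
#' A fraction of the target population's haplotypes (the carriers) receive a
#' shared core haplotype over `focal position +/- half_length_mb`, with the
#' derived (A1 = 1) allele at the focus; non-carriers are untouched. The core
#' pattern is the first carrier's pre-sweep haplotype, so carriers are
#' mutually identical over the core, emulating the extended haplotype
#' homozygosity of a recent sweep.
#'
#' @param panel a `HaplotypePanel`
#' @param plan a [sweep_plan()]
#' @param seed integer RNG seed
#' @return list with `panel` and `truth` (list: focal_marker, chrom, pos_bp,
#'   carrier_rows, window)
#' @export
inject_sweep <- function(panel, plan, seed) {
  stopifnot(inherits(plan, "sweep_plan"))
  m <- panel$markers
  if (is.null(plan$focal_marker)) {
    on_chr <- which(m$chrom == plan$chrom)
    if (!length(on_chr)) stop("no markers on chromosome ", plan$chrom)
    mid <- panel$chrom_lengths_mb[plan$chrom] * 5e5
    focal <- on_chr[which.min(abs(m$pos_bp[on_chr] - mid))]
  } else {
    focal <- match(plan$focal_marker, m$id)
    if (is.na(focal)) stop("focal marker not found: ", plan$focal_marker)
  }
  chr <- m$chrom[focal]; pos <- m$pos_bp[focal]
  half_bp <- plan$half_length_mb * 1e6
  if (pos - half_bp < 0 || pos + half_bp > panel$chrom_lengths_mb[chr] * 1e6)
    warning("sweep core truncated at chromosome boundary")
  window <- which(m$chrom == chr & abs(m$pos_bp - pos) <= half_bp)
  pop_rows <- which(panel$samples$population == plan$population)
  if (!length(pop_rows)) stop("population not found: ", plan$population)
  hap_rows <- as.vector(rbind(2L * pop_rows - 1L, 2L * pop_rows))
  n_car <- round(plan$carrier_freq * length(hap_rows))
  truth <- list(focal_marker = m$id[focal], chrom = chr, pos_bp = pos,
                carrier_rows = integer(0), window = range(window))
  if (n_car > 0) {
    carriers <- with_seed(seed, sample(hap_rows, n_car))
    core <- panel$haplotypes[carriers[1], window]
    core[window == focal] <- 1L
    panel$haplotypes[carriers, window] <-
      matrix(core, n_car, length(window), byrow = TRUE)
    panel$haplotypes[carriers, focal] <- 1L
    truth$carrier_rows <- sort(carriers)
  }
  list(panel = panel, truth = truth)
}

#' Write a haplotype panel as transposed-haplotype TSV
#'
#' One row per marker (id, chrom, pos_bp) followed by one 0/1 column per
#' haplotype, named `<sample>_1` / `<sample>_2`.
#'
#' @param panel a `HaplotypePanel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_haplotypes <- function(panel, path) {
  hap_names <- paste(rep(panel$samples$sample_id, each = 2), 1:2, sep = "_")
  df <- cbind(panel$markers[, c("id", "chrom", "pos_bp")],
              as.data.frame(t(panel$haplotypes)))
  names(df)[-(1:3)] <- hap_names
  write_tsv(df, path)
}
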