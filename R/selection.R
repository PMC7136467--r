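#' Selection-scan configuration
#'
#' @param local_pop label of the local breed under scrutiny
#' @param commercial_pops labels pooled into the "commercial" contrast group
#' @param top_n_fst number of top F_ST outlier SNPs to keep
#' @param erohi_rule `"fence"` (Tukey upper fence Q3 + k*IQR, default) or
#'   `"percentile"`
#' @param erohi_k fence multiplier
#' @param erohi_percentile percentile for the alternative rule
#' @param maf_min minimum minor-allele frequency for scanned SNPs
#' @param ehh_floor EHH truncation level
#' @param n_freq_bins number of equal-width derived-frequency bins for iHS
#'   standardization
#' @param min_bin_size bins with fewer SNPs are merged with their neighbor
#' @param log10p_threshold significance threshold on -log10 p
#' @param window_mb width of candidate windows around outlier SNPs
#' @return a `ScanConfig` list
#' @export
scan_config <- function(local_pop = NULL, commercial_pops = NULL,
                        top_n_fst = 30L, erohi_rule = c("fence", "percentile"),
                        erohi_k = 1.5, erohi_percentile = 0.99,
                        maf_min = 0.05, ehh_floor = 0.05,
                        n_freq_bins = 20L, min_bin_size = 20L,
                        log10p_threshold = 4.0, window_mb = 0.1) {
  structure(list(local_pop = local_pop, commercial_pops = commercial_pops,
                 top_n_fst = as.integer(top_n_fst),
                 erohi_rule = match.arg(erohi_rule), erohi_k = erohi_k,
                 erohi_percentile = erohi_percentile, maf_min = maf_min,
                 ehh_floor = ehh_floor, n_freq_bins = as.integer(n_freq_bins),
                 min_bin_size = as.integer(min_bin_size),
                 log10p_threshold = log10p_threshold, window_mb = window_mb),
            class = "ScanConfig")
}

#' Top F_ST outlier SNPs, local breed versus pooled commercial breeds
#'
#' Per-locus Weir-Cockerham theta between the local population and the pooled
#' commercial group; the `top_n` largest values are returned, ties at the
#' cutoff broken by (chrom, pos) ascending.
#'
#' @param ds a [genotype_dataset()]
#' @param local_pop local breed label
#' @param commercial_pops labels pooled as the commercial contrast
#' @param top_n outliers to keep (default 30); when fewer loci have defined
#'   theta, all are returned with a warning
#' @return data.frame: id, chrom, pos_bp, theta (sorted by theta descending)
#' @export
fst_outliers <- function(ds, local_pop, commercial_pops, top_n = 30L) {
  fst <- wc_fst(ds, pops = c(local_pop, "COMMERCIAL"),
                pool = list(COMMERCIAL = commercial_pops))
  pl <- fst$per_locus[!is.na(fst$per_locus$theta), ]
  if (nrow(pl) < top_n) {
    warning("only ", nrow(pl), " loci with defined theta; returning all")
    top_n <- nrow(pl)
  }
  o <- order(-pl$theta, pl$chrom, pl$pos_bp)
  out <- pl[o[seq_len(top_n)], c("id", "chrom", "pos_bp", "theta")]
  rownames(out) <- NULL
  out
}

#' ROH-island (eROHi) outlier SNPs
#'
#' Flags SNPs whose within-population ROH incidence exceeds the Tukey upper
#' fence `Q3 + k * IQR` of the genome-wide incidence distribution (roughly
#' the upper 1\% under a normal model), or the given percentile under the
#' alternative rule. Contiguous flagged SNPs are grouped into islands.
#'
#' @param incidence named incidence vector from [roh_incidence()]
#' @param markers marker data.frame aligned with `incidence`
#' @param cfg a [scan_config()]
#' @return list with `outliers` (marker ids), `threshold`, and `islands`
#'   (data.frame chrom, start_bp, end_bp, n_snps)
#' @export
erohi_outliers <- function(incidence, markers, cfg = scan_config()) {
  stopifnot(length(incidence) == nrow(markers))
  thr <- if (cfg$erohi_rule == "fence") {
    q <- stats::quantile(incidence, c(0.25, 0.75), names = FALSE)
    q[2] + cfg$erohi_k * (q[2] - q[1])
  } else {
    stats::quantile(incidence, cfg$erohi_percentile, names = FALSE)
  }
  flag <- incidence > thr
  ids <- markers$id[flag]
  islands <- data.frame(chrom = integer(0), start_bp = integer(0),
                        end_bp = integer(0), n_snps = integer(0))
  if (any(flag)) {
    idx <- which(flag)
    brk <- c(TRUE, diff(idx) != 1 | diff(markers$chrom[idx]) != 0)
    grp <- cumsum(brk)
    islands <- do.call(rbind, lapply(split(idx, grp), function(ii) {
      data.frame(chrom = markers$chrom[ii[1]],
                 start_bp = markers$pos_bp[ii[1]],
                 end_bp = markers$pos_bp[ii[length(ii)]],
                 n_snps = length(ii))
    }))
    rownames(islands) <- NULL
  }
  list(outliers = ids, threshold = unname(thr), islands = islands)
}

# group-refinement step shared by EHH variants: returns grouped homozygosity
hap_homozygosity <- function(groups) {
  tab <- tabulate(groups)
  n <- length(groups)
  sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
}

ehh_decay_one_side <- function(hap, markers, core_idx, rows, idx_side,
                               floor) {
  # rows: haplotype rows tracked; idx_side: marker indices walking outward
  groups <- rep(1L, length(rows))
  dist_bp <- 0
  ehh <- 1
  for (m in idx_side) {
    al <- hap[rows, m]
    groups <- match(paste(groups, al), unique(paste(groups, al)))
    e <- hap_homozygosity(groups)
    dist_bp <- c(dist_bp, abs(markers$pos_bp[m] - markers$pos_bp[core_idx]))
    ehh <- c(ehh, e)
    if (e < floor) break
  }
  list(dist_bp = dist_bp, ehh = ehh)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at distance d is the probability that two random distinct carrier
#' haplotypes are identical over every SNP between the core and d; it is
#' computed marker-by-marker outward in both directions, truncated when EHH
#' falls below `floor` (the crossing point is kept as the terminal
#' integration node) or at the chromosome end. iHH is the trapezoid integral
#' of EHH against physical distance (Mb), both directions summed.
#'
#' @param panel a `HaplotypePanel`
#' @param core marker id of the core SNP
#' @param allele core allele defining the carriers (1 = A1, 0 = A2), or
#'   `NULL` for the site-specific variant over all haplotypes (EHHS,
#'   normalized by core-site homozygosity)
#' @param floor EHH truncation level (default 0.05)
#' @return an `EhhDecay` list: `core`, `allele`, `left`/`right`
#'   (data.frames dist_bp, ehh), `ihh` (Mb)
#' @export
ehh <- function(panel, core, allele = 1L, floor = 0.05) {
  m <- panel$markers
  core_idx <- match(core, m$id)
  if (is.na(core_idx)) stop("core marker not found: ", core)
  chr <- m$chrom[core_idx]
  on_chr <- which(m$chrom == chr)
  hap <- panel$haplotypes
  if (is.null(allele)) {
    rows <- seq_len(nrow(hap))
    core_groups <- hap[rows, core_idx] + 1L
    h0 <- hap_homozygosity(core_groups)
    if (h0 == 0) stop("monomorphic-free core homozygosity is zero")
  } else {
    rows <- which(hap[, core_idx] == allele)
    if (length(rows) < 2)
      return(structure(list(core = core, allele = allele, left = NULL,
                            right = NULL, ihh = NA_real_, n_carriers =
                              length(rows)), class = "EhhDecay"))
  }
  left_idx <- rev(on_chr[on_chr < core_idx])
  right_idx <- on_chr[on_chr > core_idx]
  if (is.null(allele)) {
    # EHHS: start from the core-allele partition, normalize by H(0)
    side <- function(idx_side) {
      groups <- core_groups
      dist_bp <- 0; eh <- 1
      for (mm in idx_side) {
        al <- hap[rows, mm]
        groups <- match(paste(groups, al), unique(paste(groups, al)))
        e <- hap_homozygosity(groups) / h0
        dist_bp <- c(dist_bp, abs(m$pos_bp[mm] - m$pos_bp[core_idx]))
        eh <- c(eh, e)
        if (e < floor) break
      }
      list(dist_bp = dist_bp, ehh = eh)
    }
    L <- side(left_idx); R <- side(right_idx)
  } else {
    L <- ehh_decay_one_side(hap, m, core_idx, rows, left_idx, floor)
    R <- ehh_decay_one_side(hap, m, core_idx, rows, right_idx, floor)
  }
  ihh <- (trapezoid(L$dist_bp, L$ehh) + trapezoid(R$dist_bp, R$ehh)) / 1e6
  structure(list(core = core, allele = allele,
                 left = data.frame(dist_bp = L$dist_bp, ehh = L$ehh),
                 right = data.frame(dist_bp = R$dist_bp, ehh = R$ehh),
                 ihh = ihh, n_carriers = length(rows)),
            class = "EhhDecay")
}

#' @export
print.EhhDecay <- function(x, ...) {
  cat(sprintf("EhhDecay at %s (allele %s): iHH = %.4f Mb over %d carriers\n",
              x$core, if (is.null(x$allele)) "site" else x$allele,
              x$ihh, x$n_carriers))
  invisible(x)
}

standardize_in_bins <- function(stat, freq, n_bins, min_bin) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(freq, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  # merge sparse bins with their left neighbor (leftmost merges right)
  repeat {
    sizes <- tabulate(bin, n_bins)
    present <- which(sizes > 0)
    small <- present[sizes[present] < min_bin]
    if (!length(small) || length(present) == 1) break
    s <- small[1]
    lower <- present[present < s]
    target <- if (length(lower)) max(lower) else min(present[present > s])
    bin[bin == s] <- target
  }
  z <- stat
  for (b in unique(bin)) {
    i <- bin == b
    mu <- mean(stat[i]); sdv <- stats::sd(stat[i])
    z[i] <- if (is.na(sdv) || sdv == 0) 0 else (stat[i] - mu) / sdv
  }
  list(z = z, bin = bin)
}

#' Within-population integrated haplotype score (iHS) scan
#'
#' For every SNP above the minor-allele-frequency floor, computes
#' `ln(iHH_ancestral / iHH_derived)`; true ancestral states are unknown on a
#' SNP chip, so by default the minor allele plays the derived role (|iHS| is
#' polarity-invariant and p-values are two-sided, so significance calls do
#' not depend on this choice). Scores are standardized to zero mean and unit
#' sd within equal-width derived-frequency bins, and `-log10` two-sided
#' normal p-values are reported.
#'
#' @param panel a `HaplotypePanel` (one population)
#' @param cfg a [scan_config()]
#' @return an `IhsResult` data.frame: id, chrom, pos_bp, freq_derived, bin,
#'   unstandardized, ihs, log10p, significant
#' @export
ihs_scan <- function(panel, cfg = scan_config()) {
  m <- panel$markers
  freq1 <- colMeans(panel$haplotypes)
  maf <- pmin(freq1, 1 - freq1)
  scan <- which(maf >= cfg$maf_min)
  res <- lapply(scan, function(j) {
    derived <- if (freq1[j] <= 0.5) 1L else 0L   # minor allele as derived
    eh_d <- ehh(panel, m$id[j], derived, cfg$ehh_floor)
    eh_a <- ehh(panel, m$id[j], 1L - derived, cfg$ehh_floor)
    if (is.na(eh_d$ihh) || is.na(eh_a$ihh) ||
        eh_d$ihh <= 0 || eh_a$ihh <= 0) return(NULL)
    data.frame(id = m$id[j], chrom = m$chrom[j], pos_bp = m$pos_bp[j],
               freq_derived = if (derived == 1L) freq1[j] else 1 - freq1[j],
               unstandardized = log(eh_a$ihh / eh_d$ihh),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) stop("no scannable SNPs")
  st <- standardize_in_bins(res$unstandardized, res$freq_derived,
                            cfg$n_freq_bins, cfg$min_bin_size)
  res$bin <- st$bin
  res$ihs <- st$z
  res$log10p <- -log10(2 * stats::pnorm(-abs(res$ihs)))
  res$significant <- res$log10p >= cfg$log10p_threshold
  class(res) <- c("IhsResult", class(res))
  res
}

#' Across-population integrated EHHS ratio (Rsb) scan
#'
#' For every shared SNP, the log-ratio of integrated site-specific EHH
#' (`ln(iES_A / iES_B)`), median-centered and sd-scaled genome-wide, with
#' `-log10` two-sided normal p-values. SNPs with undefined iES (monomorphic
#' flanks) are skipped and counted in `attr(, "n_skipped")`.
#'
#' @param panel_a,panel_b `HaplotypePanel`s over the same marker map
#' @param cfg a [scan_config()]
#' @return an `RsbResult` data.frame: id, chrom, pos_bp, unstandardized, rsb,
#'   log10p, significant
#' @export
rsb_scan <- function(panel_a, panel_b, cfg = scan_config()) {
  if (!identical(panel_a$markers[c("id", "chrom", "pos_bp")],
                 panel_b$markers[c("id", "chrom", "pos_bp")]))
    stop("panels have different marker maps")
  m <- panel_a$markers
  n_skipped <- 0L
  res <- lapply(seq_len(nrow(m)), function(j) {
    ies <- vapply(list(panel_a, panel_b), function(p) {
      f <- mean(p$haplotypes[, j])
      if (f == 0 || f == 1) return(NA_real_)   # monomorphic core
      ehh(p, m$id[j], allele = NULL, floor = cfg$ehh_floor)$ihh
    }, numeric(1))
    if (anyNA(ies) || any(ies <= 0)) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    data.frame(id = m$id[j], chrom = m$chrom[j], pos_bp = m$pos_bp[j],
               unstandardized = log(ies[1] / ies[2]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) stop("no scannable SNPs")
  sdv <- stats::sd(res$unstandardized)
  res$rsb <- if (is.na(sdv) || sdv == 0) rep(0, nrow(res)) else
    (res$unstandardized - stats::median(res$unstandardized)) / sdv
  res$log10p <- -log10(2 * stats::pnorm(-abs(res$rsb)))
  res$significant <- res$log10p >= cfg$log10p_threshold
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("RsbResult", class(res))
  res
}

#' Cross-method overlap report with candidate windows
#'
#' Intersections of named outlier SNP sets (all pairs and the full k-way
#' intersection), plus a candidate window of `window_mb` centered on each
#' outlier SNP with the contained markers listed (inclusive bounds).
#'
#' @param sets named list (>= 2) of outlier marker-id vectors
#' @param markers marker data.frame (id, chrom, pos_bp)
#' @param window_mb window width (default 0.1)
#' @return an `OverlapReport` list: `sets`, `pairwise` (data.frame), `full`
#'   (k-way intersection), `windows` (data.frame id, chrom, start_bp, end_bp,
#'   n_contained, contained)
#' @export
overlap_report <- function(sets, markers, window_mb = 0.1) {
  if (length(sets) < 2) stop("need at least two named sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    ov <- intersect(sets[[p[1]]], sets[[p[2]]])
    data.frame(set_a = p[1], set_b = p[2], n_overlap = length(ov),
               overlap = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  full <- Reduce(intersect, sets)
  all_out <- sort(unique(unlist(sets)))
  half_bp <- window_mb / 2 * 1e6
  windows <- do.call(rbind, lapply(all_out, function(id) {
    i <- match(id, markers$id)
    if (is.na(i)) return(NULL)
    lo <- markers$pos_bp[i] - half_bp
    hi <- markers$pos_bp[i] + half_bp
    inside <- markers$id[markers$chrom == markers$chrom[i] &
                           markers$pos_bp >= lo & markers$pos_bp <= hi]
    data.frame(id = id, chrom = markers$chrom[i],
               start_bp = lo, end_bp = hi,
               n_contained = length(inside),
               contained = paste(inside, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  structure(list(sets = sets, pairwise = pairwise, full = full,
                 windows = windows),
            class = "OverlapReport")
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("OverlapReport:\n")
  for (nm in names(x$sets))
    cat(sprintf("  %s: %d outliers\n", nm, length(x$sets[[nm]])))
  for (r in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %s & %s: %d shared\n", x$pairwise$set_a[r],
                x$pairwise$set_b[r], x$pairwise$n_overlap[r]))
  cat(sprintf("  all methods: %d shared\n", length(x$full)))
  invisible(x)
}
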