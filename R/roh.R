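#' Runs-of-homozygosity calling parameters
#'
#' Defaults encode a 60K-chip rule set: a run needs at least 15 consecutive
#' homozygous SNPs at an average density of one SNP per 0.1 Mb with no
#' adjacent-SNP gap above 1 Mb; runs are called in three length classes
#' (>4 Mb, >8 Mb, >16 Mb) allowing 1, 2 and 4 missing calls per run
#' respectively. No heterozygous call is tolerated inside a run. The genome
#' length (2,444.5 Mb over 18 autosomes) is the F_ROH denominator.
#'
#' @param min_snps minimum SNPs per run
#' @param max_gap_mb maximum adjacent-SNP gap inside a run (Mb)
#' @param density_mb_per_snp maximum average Mb per SNP inside a run
#' @param classes data.frame with columns `min_length_mb`, `allowed_missing`,
#'   sorted ascending in length with non-decreasing allowances
#' @param genome_length_mb autosomal genome length covered by the chip (Mb)
#' @return a `RohParams` list
#' @export
roh_params <- function(min_snps = 15L, max_gap_mb = 1.0,
                       density_mb_per_snp = 0.1,
                       classes = data.frame(min_length_mb = c(4, 8, 16),
                                            allowed_missing = c(1L, 2L, 4L)),
                       genome_length_mb = 2444.5) {
  if (is.unsorted(classes$min_length_mb, strictly = TRUE))
    stop("classes must be sorted ascending by min_length_mb")
  if (is.unsorted(classes$allowed_missing))
    stop("missing-call allowances must be non-decreasing")
  structure(list(min_snps = as.integer(min_snps), max_gap_mb = max_gap_mb,
                 density_mb_per_snp = density_mb_per_snp, classes = classes,
                 genome_length_mb = genome_length_mb),
            class = "RohParams")
}

#' Detect runs of homozygosity for one length class
#'
#' Per individual and chromosome, returns every maximal interval that
#' satisfies all run constraints of the given class: no heterozygote, at most
#' the class's missing-call allowance, adjacent gaps within `max_gap_mb`,
#' at least `min_snps` SNPs, span at least the class's minimum length, and
#' average density within `density_mb_per_snp`. Maximality means no one-SNP
#' extension satisfies all constraints. Missing calls inside a run do not
#' break homozygosity but count against the allowance, and their positions
#' contribute to run length.
#'
#' @param ds a [genotype_dataset()] with markers sorted by (chrom, pos_bp)
#' @param params a [roh_params()]
#' @param class_index row of `params$classes` to apply (1 = shortest class)
#' @return data.frame of `RohSegment` rows: sample_id, chrom, start_bp,
#'   end_bp, n_snps, n_missing, length_mb, class_label
#' @export
detect_roh <- function(ds, params = roh_params(), class_index = 1L) {
  m <- ds$markers
  o <- order(m$chrom, m$pos_bp)
  if (!identical(o, seq_len(nrow(m))))
    stop("markers must be sorted by (chrom, pos_bp)")
  cls <- params$classes[class_index, ]
  label <- sprintf(">%gMb", cls$min_length_mb)
  out <- list()
  chroms <- unique(m$chrom)
  for (chr in chroms) {
    idx <- which(m$chrom == chr)
    pos <- as.numeric(m$pos_bp[idx])
    for (i in seq_len(n_samples(ds))) {
      g <- ds$calls[i, idx]
      g[is.na(g)] <- -1L
      seg <- roh_scan_cpp(g, pos,
                          params$min_snps, params$max_gap_mb * 1e6,
                          params$density_mb_per_snp * 1e6,
                          cls$min_length_mb * 1e6,
                          as.integer(cls$allowed_missing))
      if (nrow(seg) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = ds$samples$sample_id[i], chrom = chr,
        start_bp = m$pos_bp[idx][seg[, "start_idx"]],
        end_bp = m$pos_bp[idx][seg[, "end_idx"]],
        n_snps = seg[, "n_snps"], n_missing = seg[, "n_missing"],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), n_missing = integer(0),
                      length_mb = numeric(0), class_label = character(0)))
  seg <- do.call(rbind, out)
  seg$length_mb <- (seg$end_bp - seg$start_bp) / 1e6
  seg$class_label <- label
  seg[order(seg$sample_id, seg$chrom, seg$start_bp), , drop = FALSE]
}

#' Merge per-class ROH calls into per-individual interval unions
#'
#' Takes the segments of the class-specific passes and coalesces, per
#' individual and chromosome, all overlapping intervals into their bp union,
#' so that a region found by several classes is counted once.
#'
#' @param segments data.frame as returned by [detect_roh()] (classes may be
#'   concatenated with `rbind`)
#' @return data.frame: sample_id, chrom, start_bp, end_bp, length_mb
#' @export
merge_class_calls <- function(segments) {
  if (nrow(segments) == 0)
    return(data.frame(sample_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      length_mb = numeric(0)))
  pieces <- lapply(split(segments, segments[c("sample_id", "chrom")],
                         drop = TRUE), function(d) {
    red <- IRanges::reduce(IRanges::IRanges(d$start_bp, d$end_bp))
    data.frame(sample_id = d$sample_id[1], chrom = d$chrom[1],
               start_bp = IRanges::start(red), end_bp = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  un <- do.call(rbind, pieces)
  rownames(un) <- NULL
  un$length_mb <- (un$end_bp - un$start_bp) / 1e6
  un[order(un$sample_id, un$chrom, un$start_bp), , drop = FALSE]
}

#' Genomic inbreeding coefficients from merged ROH
#'
#' For each individual, `F_ROH>XMb` is the summed length of union segments at
#' least X Mb long divided by the genome length; the 4-8 Mb coefficient is
#' the difference `F_ROH>4Mb - F_ROH>8Mb`, separating "remote" from "recent"
#' (within roughly seven generations) inbreeding.
#'
#' @param union_segments data.frame from [merge_class_calls()]
#' @param params a [roh_params()] (supplies thresholds and genome length)
#' @param sample_ids individuals to report (default: those present in
#'   `union_segments`); individuals without segments get zeros
#' @return data.frame of `InbreedingRecord` rows: sample_id, froh_gt4,
#'   froh_gt8, froh_4to8, froh_gt16
#' @export
froh <- function(union_segments, params = roh_params(), sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(union_segments$sample_id)
  thr <- c(4, 8, 16)   # the record's fixed length classes (Mb)
  glen <- params$genome_length_mb
  one <- function(sid) {
    lens <- union_segments$length_mb[union_segments$sample_id == sid]
    vapply(thr, function(x) sum(lens[lens >= x]) / glen, numeric(1))
  }
  vals <- t(vapply(sample_ids, one, numeric(length(thr))))
  data.frame(sample_id = sample_ids,
             froh_gt4 = vals[, 1], froh_gt8 = vals[, 2],
             froh_4to8 = vals[, 1] - vals[, 2], froh_gt16 = vals[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-SNP ROH incidence within a population
#'
#' The fraction of a population's individuals whose merged ROH intervals
#' cover each marker position; the raw material of the ROH-island (eROHi)
#' selection scan.
#'
#' @param union_segments data.frame from [merge_class_calls()], called for
#'   all individuals of the population (shortest class by default upstream)
#' @param ds a [genotype_dataset()] providing the marker map
#' @param population population label
#' @return numeric vector of length `n_markers(ds)`, named by marker id
#' @export
roh_incidence <- function(union_segments, ds, population) {
  ids <- ds$samples$sample_id[ds$samples$population == population]
  if (!length(ids)) stop("population not found: ", population)
  m <- ds$markers
  cov <- numeric(nrow(m))
  segs <- union_segments[union_segments$sample_id %in% ids, , drop = FALSE]
  for (chr in unique(segs$chrom)) {
    on_chr <- which(m$chrom == chr)
    if (!length(on_chr)) next
    sc <- segs[segs$chrom == chr, ]
    q <- IRanges::IRanges(m$pos_bp[on_chr], width = 1L)
    for (sid in unique(sc$sample_id)) {
      s <- sc[sc$sample_id == sid, ]
      hit <- IRanges::overlapsAny(q, IRanges::IRanges(s$start_bp, s$end_bp))
      cov[on_chr] <- cov[on_chr] + hit
    }
  }
  stats::setNames(cov / length(ids), m$id)
}

#' Full ROH calling and inbreeding workflow
#'
#' Runs [detect_roh()] for every length class, merges the calls, and computes
#' per-individual inbreeding records.
#'
#' @param ds a [genotype_dataset()]
#' @param params a [roh_params()]
#' @return list with `segments` (all class passes), `union` (merged
#'   intervals) and `inbreeding` (records for every sample in `ds`)
#' @export
call_roh <- function(ds, params = roh_params()) {
  segs <- do.call(rbind, lapply(seq_len(nrow(params$classes)),
                                function(ci) detect_roh(ds, params, ci)))
  un <- merge_class_calls(segs)
  rec <- froh(un, params, sample_ids = ds$samples$sample_id)
  list(segments = segs, union = un, inbreeding = rec)
}

#' Write ROH segments as TSV
#' @param segments data.frame from [detect_roh()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_roh <- function(segments, path) write_tsv(segments, path)

#' Write ROH segments as BED (0-based half-open)
#' @param segments data.frame from [detect_roh()] or [merge_class_calls()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L,  # BED is 0-based
                    end = segments$end_bp,
                    name = segments$sample_id)
  write_tsv(bed, path, col.names = FALSE)
}
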