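#' Pipeline configuration
#'
#' Either `input_prefix`/`input_format` (a PLINK fileset, optionally with a
#' population table) or `simulate` (a [sim_config()]) supplies the data.
#' Stage toggles switch the analysis stages on or off; per-stage parameter
#' objects carry each module's settings. A single global seed fans out to
#' per-stage streams by fixed offsets so stage-level stochasticity is
#' isolated.
#'
#' @param out_dir output directory
#' @param input_prefix optional PLINK prefix
#' @param input_format `"binary"` or `"text"`
#' @param pop_table optional population-table path
#' @param simulate optional [sim_config()] used when no input is given
#' @param stages character vector among `c("mds", "admixture", "roh", "fst",
#'   "scan")` (QC always runs)
#' @param qc list of QC thresholds (see [qc_pipeline()])
#' @param thin_to optional marker count for admixture thinning
#' @param admixture an [admixture_spec()] (required when stage enabled)
#' @param roh a [roh_params()]
#' @param scan a [scan_config()] (required when stage enabled)
#' @param seed global integer seed
#' @return a `PipelineConfig` list
#' @export
pipeline_config <- function(out_dir, input_prefix = NULL,
                            input_format = "binary", pop_table = NULL,
                            simulate = NULL,
                            stages = c("mds", "roh", "fst"),
                            qc = list(max_snp_missing = 0.10,
                                      max_sample_missing = 0.05),
                            thin_to = NULL, admixture = NULL,
                            roh = roh_params(), scan = NULL, seed = 1L) {
  known <- c("mds", "admixture", "roh", "fst", "scan")
  if (length(bad <- setdiff(stages, known)))
    stop("unknown stages: ", paste(bad, collapse = ", "))
  if (is.null(input_prefix) && is.null(simulate))
    stop("either input_prefix or simulate must be given")
  if ("admixture" %in% stages && is.null(admixture))
    stop("admixture stage enabled but no admixture spec given")
  if ("scan" %in% stages && is.null(scan))
    stop("scan stage enabled but no scan config given")
  structure(list(out_dir = out_dir, input_prefix = input_prefix,
                 input_format = input_format, pop_table = pop_table,
                 simulate = simulate, stages = stages, qc = qc,
                 thin_to = thin_to, admixture = admixture, roh = roh,
                 scan = scan, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' A human-editable key-value file mirroring [pipeline_config()] arguments;
#' nested blocks `simulate`, `admixture`, `roh` and `scan` are passed to the
#' corresponding constructors.
#'
#' @param path YAML file
#' @return a `PipelineConfig`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$admixture)) y$admixture <- do.call(admixture_spec, y$admixture)
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  if (!is.null(y$scan)) y$scan <- do.call(scan_config, y$scan)
  do.call(pipeline_config, y)
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes QC, then the enabled stages in order (MDS, admixture, ROH,
#' F_ST/tree, selection scan), writing every artifact plus a JSON manifest of
#' output checksums under `config$out_dir`. Any stage error aborts with the
#' stage name; the manifest written so far is preserved.
#'
#' @param config a [pipeline_config()]
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_path <- out("run.log")
  cat("", file = log_path)
  writeLines(yaml::as.yaml(config_echo(config)), out("config.yaml"))
  manifest <- character(0)
  add <- function(f) manifest <<- c(manifest, f)
  stage <- "input"
  result <- tryCatch({
    log_line(log_path, stage, "start")
    sim <- NULL
    if (!is.null(config$input_prefix)) {
      ds <- read_plink(config$input_prefix, config$input_format,
                       config$pop_table)
    } else {
      sim <- simulate_panel(config$simulate)
      ds <- sim$dataset
      write_plink(ds, out("panel"), "binary")
      add("panel.bed"); add("panel.bim"); add("panel.fam")
    }
    log_line(log_path, stage, sprintf("%d samples x %d SNPs",
                                      n_samples(ds), n_markers(ds)))

    stage <- "qc"
    log_line(log_path, stage, "start")
    qc <- do.call(qc_pipeline, c(list(ds), config$qc))
    ds <- qc$dataset
    write_qc_report(qc$reports$snp, out("qc_snps.tsv")); add("qc_snps.tsv")
    write_qc_report(qc$reports$sample, out("qc_samples.tsv"))
    add("qc_samples.tsv")
    log_line(log_path, stage, sprintf("kept %d samples x %d SNPs",
                                      n_samples(ds), n_markers(ds)))

    if ("mds" %in% config$stages) {
      stage <- "mds"
      log_line(log_path, stage, "start")
      mds <- classical_mds(ibs_matrix(ds))
      write_mds(mds, out("mds.tsv"), ds); add("mds.tsv")
    }

    if ("admixture" %in% config$stages) {
      stage <- "admixture"
      log_line(log_path, stage, "start")
      ds_adm <- if (!is.null(config$thin_to) &&
                    config$thin_to < n_markers(ds))
        thin_snps(ds, config$thin_to, stage_seed(config$seed, 11)) else ds
      spec <- config$admixture
      spec$seed <- stage_seed(config$seed, 12)
      runs <- admixture_runs(ds_adm, spec)
      write_q_matrix(runs$aligned$Q_mean, out("Q.tsv"), ds_adm); add("Q.tsv")
      write_tsv(data.frame(run = seq_along(runs$ln_evidence),
                           ln_evidence = runs$ln_evidence),
                out("admixture_evidence.tsv"))
      add("admixture_evidence.tsv")
    }

    roh_res <- NULL
    if ("roh" %in% config$stages) {
      stage <- "roh"
      log_line(log_path, stage, "start")
      roh_res <- call_roh(ds, config$roh)
      write_roh(roh_res$segments, out("roh.tsv")); add("roh.tsv")
      write_tsv(roh_res$inbreeding, out("inbreeding.tsv"))
      add("inbreeding.tsv")
    }

    fst_mat <- NULL
    if ("fst" %in% config$stages) {
      stage <- "fst"
      log_line(log_path, stage, "start")
      fst_mat <- pairwise_fst_matrix(ds)
      write_tsv(data.frame(population = rownames(fst_mat$matrix),
                           fst_mat$matrix, check.names = FALSE),
                out("fst_matrix.tsv"))
      add("fst_matrix.tsv")
      if (nrow(fst_mat$matrix) >= 3) {
        tree <- nj_tree(reynolds_distance(fst_mat$matrix))
        write_newick(tree, out("tree.nwk")); add("tree.nwk")
      }
    }

    if ("scan" %in% config$stages) {
      stage <- "scan"
      log_line(log_path, stage, "start")
      cfg <- config$scan
      outl <- fst_outliers(ds, cfg$local_pop, cfg$commercial_pops,
                           cfg$top_n_fst)
      write_tsv(outl, out("scan_fst_outliers.tsv"))
      add("scan_fst_outliers.tsv")
      sets <- list(fst = outl$id)
      if (!is.null(roh_res)) {
        inc <- roh_incidence(roh_res$union, ds, cfg$local_pop)
        er <- erohi_outliers(inc, ds$markers, cfg)
        write_tsv(data.frame(id = ds$markers$id, chrom = ds$markers$chrom,
                             pos_bp = ds$markers$pos_bp, incidence = inc),
                  out("scan_erohi_incidence.tsv"))
        add("scan_erohi_incidence.tsv")
        sets$erohi <- er$outliers
      }
      if (!is.null(sim)) {  # haplotype scans need phased input
        pl <- subset_panel_populations(sim$panel, cfg$local_pop)
        pl$markers <- pl$markers  # scans run on the QC'd marker set
        keep <- match(ds$markers$id, pl$markers$id)
        pl <- haplotype_panel(pl$markers[keep, ],
                              pl$haplotypes[, keep, drop = FALSE],
                              pl$samples, pl$chrom_lengths_mb)
        ihs <- ihs_scan(pl, cfg)
        write_tsv(as.data.frame(ihs), out("scan_ihs.tsv")); add("scan_ihs.tsv")
        sets$ihs <- ihs$id[ihs$significant]
        pc <- subset_panel_populations(sim$panel, cfg$commercial_pops)
        pc <- haplotype_panel(pc$markers[keep, ],
                              pc$haplotypes[, keep, drop = FALSE],
                              pc$samples, pc$chrom_lengths_mb)
        rsb <- rsb_scan(pl, pc, cfg)
        write_tsv(as.data.frame(rsb), out("scan_rsb.tsv")); add("scan_rsb.tsv")
        sets$rsb <- rsb$id[rsb$significant]
      }
      if (length(sets) >= 2) {
        ov <- overlap_report(sets, ds$markers, cfg$window_mb)
        write_tsv(ov$pairwise, out("scan_overlap.tsv"))
        add("scan_overlap.tsv")
      }
    }
    stage <- "manifest"
    TRUE
  }, error = function(e) {
    log_line(log_path, stage, paste("ERROR:", conditionMessage(e)))
    write_manifest(config$out_dir, manifest, out("manifest.json"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  write_manifest(config$out_dir, manifest, out("manifest.json"))
  log_line(log_path, "done", sprintf("%d artifacts", length(manifest)))
  invisible(config$out_dir)
}

config_echo <- function(config) {
  ce <- lapply(unclass(config), function(x)
    if (is.list(x)) lapply(unclass(x), unname) else x)
  ce$simulate$admixture_Q <- NULL   # matrices do not round-trip in YAML
  ce
}

write_manifest <- function(dir, files, path) {
  sums <- vapply(files, function(f)
    unname(tools::md5sum(file.path(dir, f))), character(1))
  jsonlite::write_json(as.list(stats::setNames(sums, files)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Aggregate per-breed summary table
#'
#' Mean inbreeding coefficients per population joined with each population's
#' mean pairwise F_ST.
#'
#' @param ds a [genotype_dataset()]
#' @param inbreeding data.frame from [froh()]
#' @param fst_matrix result of [pairwise_fst_matrix()]
#' @return data.frame: population, n, mean_froh_gt4, mean_froh_gt8,
#'   mean_froh_4to8, mean_froh_gt16, mean_fst
#' @export
breed_summary <- function(ds, inbreeding, fst_matrix) {
  pop <- ds$samples$population[match(inbreeding$sample_id,
                                     ds$samples$sample_id)]
  agg <- do.call(rbind, lapply(split(inbreeding, pop), function(d) {
    data.frame(n = nrow(d),
               mean_froh_gt4 = mean(d$froh_gt4),
               mean_froh_gt8 = mean(d$froh_gt8),
               mean_froh_4to8 = mean(d$froh_4to8),
               mean_froh_gt16 = mean(d$froh_gt16))
  }))
  agg$population <- rownames(agg)
  agg$mean_fst <- fst_matrix$pop_mean[agg$population]
  rownames(agg) <- NULL
  agg[c("population", "n", "mean_froh_gt4", "mean_froh_gt8",
        "mean_froh_4to8", "mean_froh_gt16", "mean_fst")]
}
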