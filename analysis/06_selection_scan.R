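#!/usr/bin/env Rscript
# Selection signatures in the local breed: top F_ST outliers against the
# pooled commercial group, ROH islands (eROHi), haplotype-based iHS and Rsb
# scans, and the cross-method overlap report.

source(file.path("analysis", "00_settings.R"))

ds <- read_plink(res_path("panel"), "binary", res_path("panel_pops.tsv"))
cfg <- SCAN_CONFIG

# F_ST outliers, local vs pooled commercial
outl <- fst_outliers(ds, cfg$local_pop, cfg$commercial_pops, cfg$top_n_fst)
write_tsv(outl, res_path("scan_fst_outliers.tsv"))

# eROHi: per-SNP ROH incidence in the local breed
roh <- call_roh(ds, ROH_PARAMS)
inc <- roh_incidence(roh$union, ds, cfg$local_pop)
er <- erohi_outliers(inc, ds$markers, cfg)
write_tsv(data.frame(id = ds$markers$id, chrom = ds$markers$chrom,
                     pos_bp = ds$markers$pos_bp, incidence = inc),
          res_path("scan_erohi_incidence.tsv"))
write_tsv(er$islands, res_path("scan_erohi_islands.tsv"))
cat(sprintf("eROHi: %d outlier SNPs in %d islands (threshold %.3f)\n",
            length(er$outliers), nrow(er$islands), er$threshold))

# haplotype scans need the phased panel; re-derive it deterministically
sim <- simulate_panel(PANEL_CONFIG)
keep <- match(ds$markers$id, sim$panel$markers$id)
panel <- haplotype_panel(sim$panel$markers[keep, ],
                         sim$panel$haplotypes[, keep, drop = FALSE],
                         sim$panel$samples, sim$panel$chrom_lengths_mb)
pl <- subset_panel_populations(panel, cfg$local_pop)
pc <- subset_panel_populations(panel, cfg$commercial_pops)

ihs <- ihs_scan(pl, cfg)
write_tsv(as.data.frame(ihs), res_path("scan_ihs.tsv"))
rsb <- rsb_scan(pl, pc, cfg)
write_tsv(as.data.frame(rsb), res_path("scan_rsb.tsv"))
cat(sprintf("iHS: %d significant SNPs; Rsb: %d significant SNPs\n",
            sum(ihs$significant), sum(rsb$significant)))

sets <- list(fst = outl$id, erohi = er$outliers,
             ihs = ihs$id[ihs$significant], rsb = rsb$id[rsb$significant])
sets <- sets[vapply(sets, length, integer(1)) > 0]
if (length(sets) >= 2) {
  ov <- overlap_report(sets, ds$markers, cfg$window_mb)
  write_tsv(ov$pairwise, res_path("scan_overlap.tsv"))
  write_tsv(ov$windows, res_path("scan_windows.tsv"))
  print(ov$pairwise[c("set_a", "set_b", "n_overlap")])
}
cat("wrote scan artifacts under", RESULTS, "\n")
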