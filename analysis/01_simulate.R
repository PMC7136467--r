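#!/usr/bin/env Rscript
# Simulate the study-like panel, run genotype QC, and write the PLINK
# fileset plus QC reports that every downstream driver reads.

source(file.path("analysis", "00_settings.R"))

sim <- simulate_panel(PANEL_CONFIG)
cat(sprintf("simulated %d samples x %d SNPs\n",
            n_samples(sim$dataset), n_markers(sim$dataset)))

qc <- qc_pipeline(sim$dataset, max_snp_missing = 0.10,
                  max_sample_missing = 0.05)
ds <- qc$dataset
cat(sprintf("post-QC: %d samples x %d SNPs\n", n_samples(ds), n_markers(ds)))

write_plink(ds, res_path("panel"), "binary")
write_pop_table(ds, res_path("panel_pops.tsv"))
write_qc_report(qc$reports$snp, res_path("qc_snps.tsv"))
write_qc_report(qc$reports$sample, res_path("qc_samples.tsv"))

# phased haplotypes for the selection scan (restricted to post-QC markers)
keep <- match(ds$markers$id, sim$panel$markers$id)
panel <- haplotype_panel(sim$panel$markers[keep, ],
                         sim$panel$haplotypes[, keep, drop = FALSE],
                         sim$panel$samples, sim$panel$chrom_lengths_mb)
write_haplotypes(panel, res_path("haplotypes.tsv"))

write_tsv(sim$truth$roh, res_path("truth_roh.tsv"))
cat("wrote", res_path("panel.*"), "\n")
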