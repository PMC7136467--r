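#!/usr/bin/env Rscript
# Runs of homozygosity and genomic inbreeding: per-class ROH calls, merged
# unions, per-individual F_ROH records and per-breed means.

source(file.path("analysis", "00_settings.R"))

ds <- read_plink(res_path("panel"), "binary", res_path("panel_pops.tsv"))

res <- call_roh(ds, ROH_PARAMS)
write_roh(res$segments, res_path("roh_segments.tsv"))
write_roh_bed(res$union, res_path("roh_union.bed"))
write_tsv(res$inbreeding, res_path("inbreeding.tsv"))

pop <- ds$samples$population[match(res$inbreeding$sample_id,
                                   ds$samples$sample_id)]
by_breed <- aggregate(res$inbreeding[c("froh_gt4", "froh_gt8",
                                       "froh_4to8", "froh_gt16")],
                      by = list(population = pop), FUN = mean)
write_tsv(by_breed, res_path("inbreeding_by_breed.tsv"))
print(by_breed)
cat("wrote", res_path("inbreeding.tsv"), "\n")
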