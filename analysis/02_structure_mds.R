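#!/usr/bin/env Rscript
# Population structure: IBS coancestry and classical MDS of 1 - IBS.

source(file.path("analysis", "00_settings.R"))

ds <- read_plink(res_path("panel"), "binary", res_path("panel_pops.tsv"))

ibs <- ibs_matrix(ds)
mds <- classical_mds(ibs, d = 2)
write_mds(mds, res_path("mds.tsv"), ds)

cent <- aggregate(mds$coordinates,
                  by = list(population = ds$samples$population), FUN = mean)
write_tsv(cent, res_path("mds_centroids.tsv"))
print(cent)
cat("wrote", res_path("mds.tsv"), "\n")
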