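#!/usr/bin/env Rscript
# Differentiation: pairwise multilocus Weir-Cockerham F_ST, Reynolds
# distances, and the neighbor-joining breed tree.

source(file.path("analysis", "00_settings.R"))

ds <- read_plink(res_path("panel"), "binary", res_path("panel_pops.tsv"))

pw <- pairwise_fst_matrix(ds)
write_tsv(data.frame(population = rownames(pw$matrix), pw$matrix,
                     check.names = FALSE),
          res_path("fst_matrix.tsv"))
cat(sprintf("grand mean pairwise F_ST: %.4f\n", pw$grand_mean))
print(round(pw$matrix, 4))

D <- reynolds_distance(pw$matrix)
write_tsv(data.frame(population = rownames(D), as.data.frame(D),
                     check.names = FALSE),
          res_path("reynolds_matrix.tsv"))

tree <- nj_tree(D)
write_newick(tree, res_path("tree.nwk"))
cat("wrote", res_path("tree.nwk"), "\n")
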