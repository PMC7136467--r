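#!/usr/bin/env Rscript
# Model-based ancestry: thin the panel, sweep K, pick the best-supported
# number of clusters and write the aligned mean ancestry at that K.
# Chains here are short for turnaround; production settings are the
# admixture_spec() defaults (10k burn-in + 100k reps, 20 runs).

source(file.path("analysis", "00_settings.R"))

ds <- read_plink(res_path("panel"), "binary", res_path("panel_pops.tsv"))
ds_adm <- thin_snps(ds, 2000, seed = stage_seed(GLOBAL_SEED, 2))
cat(sprintf("thinned to %d SNPs for the sampler\n", n_markers(ds_adm)))

spec <- admixture_spec(K = 2, burn_in = 100L, reps = 400L, n_runs = 2L,
                       seed = stage_seed(GLOBAL_SEED, 3))
sweep <- admixture_k_sweep(ds_adm, k_range = 1:4, spec_template = spec)
write_tsv(sweep$evidence, res_path("admixture_evidence.tsv"))
if (!is.null(sweep$delta_k))
  write_tsv(sweep$delta_k, res_path("admixture_delta_k.tsv"))
cat("best K by mean ln-evidence:", sweep$best_k, "\n")

spec_best <- spec
spec_best$K <- sweep$best_k
runs <- admixture_runs(ds_adm, spec_best)
write_q_matrix(runs$aligned$Q_mean, res_path("Q.tsv"), ds_adm)
cat("wrote", res_path("Q.tsv"), "\n")
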