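# Shared settings for the analysis workflow. Source()d by every numbered
# driver; each driver can be run on its own as
#   Rscript analysis/NN_*.R
# and re-reads upstream artifacts from results/.

suppressPackageStartupMessages(library(consgen))

RESULTS <- file.path("results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

GLOBAL_SEED <- 20260501L

# Study-like synthetic panel: two local breeds (LOCAL_A strongly inbred,
# LOCAL_B moderately) and two commercial breeds, genotyped on a chip-density
# map. Sizes are kept moderate so the whole workflow runs in minutes.
PANEL_CONFIG <- sim_config(
  n_pops = 4,
  drift = c(0.30, 0.20, 0.15, 0.15),   # local breeds more drifted
  n_per_pop = 12,
  n_snps = 20000,
  chrom_lengths_mb = default_chrom_lengths_mb(1086),  # 18 autosomes, ~0.054 Mb/SNP
  pop_names = c("LOCAL_A", "LOCAL_B", "COM_1", "COM_2"),
  roh_plan = roh_plan(target_fraction = 0.25),
  missing_rate = 0.01,
  seed = stage_seed(GLOBAL_SEED, 1)
)

ROH_PARAMS <- roh_params(genome_length_mb = 1086)

SCAN_CONFIG <- scan_config(local_pop = "LOCAL_A",
                           commercial_pops = c("COM_1", "COM_2"))

res_path <- function(...) file.path(RESULTS, ...)
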