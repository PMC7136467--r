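---
title: "Methods: conservation-genomics statistics in consgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-genomics statistics in consgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented in `consgen`,
the conventions the package fixes where the literature leaves room, and the
design of the synthetic-data generator used to validate every stage. It is
a methods reference, not a tutorial; the numbered scripts under `analysis/`
show the end-to-end workflow.

# Data model

A `genotype_dataset()` holds a marker map (`id`, `chrom`, `pos_bp`, alleles
`a1`/`a2`), a sample table (`sample_id`, `population`), and an integer call
matrix with entries 0, 1, 2 or `NA`. **A call counts copies of the A1
allele.** In PLINK text input, A1 defaults to the minor allele (ties broken
lexicographically) unless a `<prefix>.a1` sidecar file pins it; binary
filesets carry A1 in the `.bim` and round-trip exactly. Markers are stored
sorted by (chromosome, position).

# Quality control

`qc_pipeline()` applies, in order: SNP filters (non-autosomal, unmapped,
call-rate, optional GenCall/GenTrain score floors), then a sample call-rate
filter, then a SNP re-check. Boundary conventions: a SNP is removed when its
missing fraction is strictly above `max_snp_missing` (default 0.10), when
GenCall ≤ 0.7, or when GenTrain ≤ 0.4; a sample is removed when strictly
above `max_sample_missing` (default 0.05). Reports satisfy
`n_in = n_out + removed` and the pipeline is idempotent.
`intersect_merge()` harmonizes two panels to shared markers, resolving
strand flips by complementing, and drops A/T–C/G (strand-ambiguous) markers
whose counted-allele frequencies disagree by more than 0.2.

# Population structure: IBS and MDS

`ibs_matrix()` computes, per pair, the mean over mutually observed loci of
`1 − |g_i − g_j| / 2`. `classical_mds()` applies Torgerson scaling to
`D = 1 − IBS`: double-center `−D²/2`, eigendecompose, scale the top-`d`
eigenvectors by the square roots of their eigenvalues. Axis signs are fixed
by forcing each axis's largest-magnitude loading positive so ordinations are
reproducible. Euclidean distance matrices are reproduced to numerical
precision; negative eigenvalues (non-Euclidean input) are reported, not used.

# Admixture with correlated allele frequencies

`fit_admixture()` implements the Pritchard-style admixture model with the
correlated-frequencies (F-model) prior: each allele copy of individual `i`
originates in cluster `k` with probability `q_ik`; cluster frequencies
`p_kl` have a Beta prior centred on an ancestral frequency `p̄_l` with
spread governed by per-cluster drift `F_k`. One Gibbs sweep updates: origin
assignments of every allele copy; rows of Q from their Dirichlet posterior;
P from its Beta posterior; `p̄`, `F_k` and the Dirichlet parameter α by
random-walk Metropolis (α uniform on (0, 10], step 0.025). Missing
genotypes contribute nothing. Defaults follow common practice (10,000
burn-in + 100,000 reps, 20 runs); tests and examples use much shorter
chains.

Conventions fixed here:

* `ln_evidence = mean(lnL) − var(lnL)/2` over the post-burn-in trace, with
  the **sample (n−1) variance**.
* `delta_k()` is the Evanno-style second difference
  `|L(K+1) − 2 L(K) + L(K−1)| / sd(L(K))` over independent runs; endpoints
  are `NA`, a zero sd yields `Inf`.
* `align_runs()` resolves label switching greedily against an incrementally
  built mean, a lightweight analog of run-averaging tools.

A practical note on choosing K: the raw evidence typically rises steeply up
to the true K and then *plateaus*, so the argmax over K of the evidence
itself is unstable between `K_true` and `K_true + 1` with short chains —
exactly the behaviour the Evanno statistic was designed around. For K
selection we therefore recommend (and validate) the ΔK rule; the per-K
evidence table is still reported.

# Runs of homozygosity and F_ROH

`detect_roh()` finds, per individual and chromosome, every **maximal**
interval satisfying: at least 15 SNPs; no heterozygote; missing calls within
the length-class allowance (1 per run >4 Mb, 2 per >8 Mb, 4 per >16 Mb);
adjacent-SNP gaps ≤ 1 Mb; span at least the class minimum; and average
density ≤ 0.1 Mb per SNP. Maximal means no one-SNP extension also satisfies
all constraints; runs are reported with SNP counts, missing counts and
lengths (`end_bp − start_bp`, Mb). The compiled scanner is validated against
a brute-force all-subintervals oracle.

`merge_class_calls()` unions the per-class calls per individual so a region
found by several classes counts once. `froh()` divides the summed union
length at each threshold (>4, >8, >16 Mb) by the chip-covered genome length
(default 2,444.5 Mb over 18 autosomes); `froh_4to8 = froh_gt4 − froh_gt8`
separates older from recent inbreeding. `roh_incidence()` gives the
per-SNP fraction of a population's individuals covered by a union segment.

# Differentiation: Weir–Cockerham F_ST, Reynolds, NJ

`wc_fst()` implements the Weir–Cockerham (1984) variance-components
estimator from per-population sample sizes, allele frequencies and observed
heterozygosities. Per locus, θ = a/(a+b+c); the multilocus estimate is the
**ratio of sums** Σa / Σ(a+b+c), not the mean of ratios. A locus
contributes when at least two populations have two or more genotyped
individuals and the denominator is nonzero; excluded loci are counted.
Reynolds distance is `−ln(1 − θ)` with negative θ mapped to 0 and θ ≥ 1
capped (default 10, counted in attributes). Trees use neighbor-joining
(`ape::nj`) on the Reynolds matrix, with small negative branch lengths
clamped to zero (raw lengths kept as an attribute).

# Selection scans

Four complementary scans, as commonly combined in livestock studies:

1. **F_ST outliers** (`fst_outliers()`): per-SNP θ between the local breed
   and the pooled commercial group; top 30 by default.
2. **eROHi / ROH islands** (`erohi_outliers()`): SNPs whose ROH incidence
   strictly exceeds the Tukey upper fence `Q3 + 1.5·IQR` (a percentile rule
   is available); contiguous flagged SNPs form islands.
3. **iHS** (`ihs_scan()`): for each SNP with MAF ≥ 0.05,
   `ln(iHH_ancestral / iHH_derived)` where iHH is the trapezoid integral of
   allele-specific EHH against physical distance (Mb), truncated when EHH
   falls below 0.05 (the crossing node is the terminal integration point).
   True ancestral states are unknown on a chip, so the **minor allele plays
   the derived role**; |iHS| is polarity-invariant and p-values two-sided,
   so significance does not depend on this. Scores are standardized within
   20 equal-width derived-frequency bins (bins under 20 SNPs merge left).
4. **Rsb** (`rsb_scan()`): `ln(iES_A / iES_B)` from site-specific EHHS
   (normalized by core-site homozygosity), median-centred and sd-scaled
   genome-wide.

Both haplotype scans report `−log10` two-sided normal p-values with the
conventional threshold 4.0, and `overlap_report()` intersects outlier sets
and builds 0.1 Mb candidate windows.

Two caveats fixed by design and worth knowing:

* **Tail calibration.** Standardization makes the null mean ≈ 0 and sd ≈ 1,
  but iHS is heavier-tailed than normal at chip-scale haplotype counts:
  on neutral panels we observe roughly 10–14 hits per 10,000 SNPs at
  −log10 p ≥ 4 rather than the nominal ≈1. The normal p-value is a ranking
  device, as in practice; genome-wide significance claims should rely on
  empirical ranks.
* **Background size.** Because iHS/Rsb are standardized genome-wide, power
  assessments are only fair when the swept region is a small fraction of
  the scanned SNPs (as in a real genome-wide panel). On a toy chromosome
  where the sweep spans several percent of all SNPs, the sweep itself
  inflates the bin standard deviations and masks its own signal.

# Synthetic-data generator

`simulate_panel()` draws ancestral frequencies `p̄ ~ U(0.05, 0.95)` and
population frequencies from the Balding–Nichols model
`p_k ~ Beta(p̄(1−F_k)/F_k, (1−p̄)(1−F_k)/F_k)` (so
`Var[p_k|p̄] = F_k p̄(1−p̄)`), then binomial haplotypes on a chip-like map
(default 45,000 SNPs over 18 autosomes, 2,444.5 Mb, ≈0.054 Mb spacing).
Options: admixed ancestry rows (`admixture_Q`), planted autozygous tracts
(`roh_plan()`: tract lengths drawn in 4–8 and 8–30 Mb classes to a target
genome fraction, one haplotype copied over its partner), planted sweeps
(`sweep_plan()`: a carrier haplotype fixed across a ±2 Mb core at carrier
frequency 0.8 by default), and uniform missingness. Linkage is absent
outside planted tracts/sweeps — adequate for validating the estimators
above, but not a coalescent simulator: background LD, allele-frequency
spectra under demography, and recombination-map heterogeneity are out of
scope. Problem sizes used in tests (populations of 16–30, panels of
2,000–45,000 SNPs) are the package's own choices for desk-scale runtimes.

All stochastic stages take a single integer seed; `stage_seed()` fans it
out deterministically (`seed·1000003 + offset`, mod 2³¹−1) so stages are
reproducible in isolation.
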