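Package: consgen
Title: Conservation Genomics of Livestock SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A workflow for conservation-genomic analysis of diploid SNP-array
    genotypes in small livestock populations: PLINK text/binary input with
    chip-style quality control, identity-by-state coancestry and classical
    multidimensional scaling, Bayesian admixture inference under the
    correlated-allele-frequency model with evidence-based choice of the number
    of clusters, runs-of-homozygosity calling with length-class missing-call
    allowances and genomic inbreeding coefficients (F_ROH), Weir-Cockerham
    F_ST with Reynolds distances and neighbor-joining trees, and a
    four-method selection-signature scan (F_ST outliers, ROH-island
    incidence, iHS, Rsb) with cross-method overlap reporting. A
    Balding-Nichols synthetic-data generator with injected autozygosity and
    selective sweeps provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    IRanges,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
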