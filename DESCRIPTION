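Package: prsoverlap
Title: Quantifying Overestimation Bias in Polygenic Risk Scores from
    Discovery-Test Sample Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for measuring how subject
    overlap and cryptic relatedness between the discovery and test cohorts
    of a polygenic risk score (PRS) study inflate its apparent predictive
    gain. Provides synthetic genotype panels with blockwise linkage
    disequilibrium, liability-threshold phenotypes at specified
    heritability and prevalence, per-variant association testing,
    clumping-and-thresholding PRS construction and scoring, PLINK-style
    method-of-moments identity-by-descent estimation (PI_HAT) for
    duplicate and relative detection, DeLong paired-AUC and Nagelkerke
    pseudo-R2 model comparisons, and orchestrated contamination,
    scale-effect, SNP-count, power and case:control-ratio experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
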