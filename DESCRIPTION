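Package: bnsem
Title: Bayesian Networks and Structural Equation Models for Multitrait
    Genomic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated Bayesian-network and structural-equation-model genomic
    evaluation of multiple quantitative traits, as used in forest tree breeding.
    Builds pedigree (A) and VanRaden genomic (G) relationship matrices, fits
    multitrait individual-tree mixed models (ABLUP/GBLUP) by Gibbs sampling with
    unstructured genetic and residual covariances and missing-record augmentation,
    decorrelates predicted breeding values through the Cholesky factor of the
    relationship matrix, learns the trait-level causal network by score-based
    search (Hill-Climbing, Tabu; Gaussian BIC and BGe scores) with bootstrap model
    averaging, fits the recursive structural equation model on the learned
    structure, and compares models by variance components, heritabilities, genetic
    correlations, DIC, breeding-value ranking and cross-validated predictive
    ability. A synthetic-data generator emulating an open-pollinated lodgepole
    pine progeny trial makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
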