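Package: kinforest
Title: Genealogy-Aware Case-Control Design and Random-Forest Variant
    Screening for Isolated Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Case-control genetic association for isolated populations with a
    known genealogy. Computes pedigree kinship coefficients, selects the set
    of controls jointly most related to the cases by solving a linear
    assignment problem (Hungarian method), and screens disease-associated
    variants with a bagging/random-forest procedure based on Bernoulli
    deviance importance with out-of-bag error backward selection. Includes
    the single-point Fisher exact genome scan with Benjamini-Hochberg,
    Storey q-value and local false discovery rate comparators, and a
    gene-dropping simulation framework (synthetic consanguineous pedigrees,
    Mendelian genotype simulation, configuration-count disease model, ROC/AUC
    method comparison) for validating the design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
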