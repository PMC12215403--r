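Package: famtrait
Title: Gene-Family Copy-Number Prediction of Binary Stress-Resistance
    Traits Across a Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking gene-family (orthogroup) copy-number
    variation to a binary stress-resistance phenotype across a species
    phylogeny. Reduces plate-reader growth curves to relative-growth
    phenotypes via empirical area under the curve, derives balanced
    binary trait classes by a dual-concentration tail rule, trains a
    native random-forest classifier with Gini-importance feature
    selection and a replicated cross-validation protocol, interprets
    per-species predictions with exact path-dependent TreeSHAP Shapley
    attributions, tests gene-count/phenotype associations with
    phylogenetic generalized least squares under Brownian motion, and
    performs hypergeometric term enrichment with a custom background.
    Includes a synthetic-data generator (Yule phylogeny, birth-death
    gene-family evolution, liability-model trait, logistic growth
    curves) so the whole pipeline can be exercised against known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    nlme,
    pROC
Config/testthat/edition: 3
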