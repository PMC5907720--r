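Package: epiCollect
Title: Collective Feature Selection for Epistatic Variant Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Collective (union-of-methods) feature selection for detecting
    epistatic SNPs in case/control genotype data. Provides heterogeneous
    feature rankers behind a single contract -- exhaustive one- and two-locus
    multifactor dimensionality reduction (MDR), the MultiSURF* Relief-family
    scorer with an optional TuRF recursive wrapper, random-forest and
    gradient-boosting variable importances, and penalized logistic regression
    with exhaustive pairwise interaction designs -- together with top-k%
    extraction and the union across methods. Includes two case/control
    genotype simulators (frequency-shift main-effect/interaction models and
    GAMETES-style pure-strict two-locus penetrance models with an additive
    third-locus main effect, stratified by ease of detection), truth-based
    sensitivity evaluation, and an end-to-end benchmark runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    ranger,
    xgboost,
    glmnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SNP, FeatureExtraction, Classification, StatisticalMethod,
    GeneticVariability
RoxygenNote: 7.3.3
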