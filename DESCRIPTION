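Package: morphome
Title: Quantitative Tumor Budding and E-Cadherin Shifting Morphome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of tumor budding and subcellular
    E-Cadherin localization ("morphome" features) in adenocarcinoma
    cohorts. Builds a per-patient cluster census from per-cell
    annotations, derives size-binned cluster counts and E-Cadherin
    pattern fractions, performs stability feature selection with
    cross-validated lasso-penalized Cox regression, dichotomizes the
    resulting linear predictor into a low/high budding grade, and
    reports multivariable and Kaplan-Meier survival analyses. Includes
    a synthetic-cohort generator that emulates the inverse
    cluster-count/cluster-size law, size-dependent E-Cadherin
    localization, and censored survival driven by planted morphome
    effects, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Survival, FeatureExtraction, Classification, Software
RoxygenNote: 7.3.3
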