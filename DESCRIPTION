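Package: rert
Title: Representative Regression Trees for Preoperative Binary Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grows, prunes and cross-validates binary regression trees whose
    leaves carry event relative frequencies, screens covariates with a random
    forest and its Total Decrease in Node Impurity importance, and extracts a
    single representative tree from a stratified-bootstrap ensemble by AUC
    (the RERT procedure), with honest nested cross-validated evaluation.
    Includes the full evaluation harness (ROC/AUC, Youden-index operating
    points, confusion metrics, DeLong and bootstrap AUC-comparison tests,
    nonparametric association tests, a logistic baseline) and a synthetic
    clinical-cohort generator with planted threshold-interaction outcomes,
    realistic skewed biomarker marginals and missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
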