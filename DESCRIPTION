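Package: adaptsig
Title: Adaptive Signature Designs with Cross-Validated Subgroup
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for biomarker adaptive signature designs in randomized
    two-arm trials: per-probe treatment-by-marker interaction screening
    (logistic, linear, or Cox models), subgroup classifiers (diagonal
    linear discriminant analysis, the adaptive-signature odds-ratio
    voting rule, and a Cox risk-score survival-probability cutoff),
    cross-validated subgroup assignment so that every patient is
    classified by a model not trained on them, a five-comparison testing
    strategy with study-wise alpha allocation between the all-patients
    and marker-positive tests, a trial simulator reproducing the
    operating characteristics of the design, and an expected
    odds-ratio-attenuation calculator quantifying the cost of classifier
    misclassification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
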