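Package: hrvaf
Title: Heart Rate Variability Analysis for Post-Operative Atrial
    Fibrillation Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for pre-operative heart-rate-variability
    (HRV) analysis aimed at post-operative atrial fibrillation (PoAF) risk
    prediction after cardiac surgery.  Reads and cleans RR-interval series,
    computes the full time-domain, autoregressive frequency-domain and
    non-linear metric battery (Poincare descriptors, heart-rate-asymmetry
    indices, approximate and sample entropy, correlation dimension,
    recurrence rate), and reproduces the cohort statistical procedure:
    normality-driven two-group test selection, univariate logistic
    screening, stepwise model selection by Akaike's information criterion,
    and ROC characterisation.  A synthetic-data module generates RR series
    with prescribed spectral band powers and patient cohorts with prescribed
    covariate and outcome structure so that every stage is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    optparse,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
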