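Package: fracrisk
Title: Short-Term Fracture Risk Prediction from Longitudinal Diagnosis-Code Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a short-term (1-2 year) fracture-risk prediction
    pipeline for longitudinal electronic health record data. Patient
    diagnosis-code histories are treated as token sequences: qualifying
    fracture events are identified with site-specific washout rules,
    labeled 2-year sliding windows are constructed around anchor events,
    code-level skip-gram embeddings and window-level distributed
    bag-of-words embeddings are learned, and fracture risk within a
    2-year horizon is predicted with a recurrent (LSTM) sequence
    classifier, gradient-boosted trees over window embeddings, simple
    demographic baselines, and a logistic-regression ensemble. Includes
    a calibrated synthetic EHR cohort generator, threshold and
    threshold-free evaluation, and a retrospective comparison of model
    flags against physician bone-health interventions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    rlang,
    stats,
    utils,
    xgboost,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
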