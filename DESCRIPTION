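Package: inclinr
Title: Inclination Analysis of Longitudinal Clinical Biomarkers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the long-term trend ("survival" or "collapse") of
    irregularly sampled clinical biomarker time series with a
    path-dependent inclination analysis: sliding windows of local states
    are scored against clinical cut-off thresholds, the empirical
    distribution of state sequences is propagated through an absorbing
    Markov chain, and the resulting inclination index is compared with a
    uniform-prior baseline.  Includes eight scoring variants, cohort-level
    collapse-rate and similarity-score analytics, a depth-limited
    decision-tree benchmark for disease-onset prediction, and a synthetic
    electronic-medical-record generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
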