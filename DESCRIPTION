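Package: casesurv
Title: Classification-Augmented Survival Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time survival analysis by person-period augmentation.
    Censored time-to-event data are expanded into a period-replicated binary
    classification problem, classifier scores are calibrated into survival
    probabilities by adjusted Bayesian binning-in-quantiles (ABBQ), and the
    calibrated per-period probabilities form individual survival curves from
    which exact survival times are estimated (threshold, gradient and
    regression estimators). Includes temporal-stratified k-fold
    cross-validation, time-weighted survival-curve accuracy metrics
    (iAUSC/mAUSC), expected calibration error, temporal SHAP-based variable
    importance, and a seeded generator of synthetic discrete-time survival
    data with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    ranger,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
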