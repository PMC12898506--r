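Package: akiews
Title: Dynamic 24-Hour ICU Acute Kidney Injury Early-Warning Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a dynamic early-warning score
    for incident acute kidney injury (AKI) in intensive-care patients.
    Implements time-respecting KDIGO staging from raw creatinine, urine-output
    and renal-replacement streams, leakage-controlled rolling prediction
    windows with patient-grouped cross-validation folds, trajectory feature
    engineering (window summaries, long-lookback slopes, piecewise slope
    change), monotonicity-constrained gradient-boosted modelling with
    SHAP-based feature selection and Platt recalibration, and a full
    evaluation harness covering discrimination, calibration, decision-curve
    net benefit, subgroup DeLong comparisons, alert lead time and alert
    burden. A synthetic ICU cohort generator with known ground truth makes
    every stage testable without access to credentialed clinical databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
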