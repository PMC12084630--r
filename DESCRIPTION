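Package: helmet
Title: Dynamic Hourly Prediction of Midline-Shift Severity After Large MCA Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hybrid ensemble learning models for edema trajectory (HELMET):
    dynamic, hourly prediction of midline-shift (MLS) severity class over
    8-hour and 24-hour horizons in patients with large middle cerebral
    artery stroke. Provides longitudinal feature engineering (forward-fill
    and 24-hour rolling maxima on an hourly grid), window-maximum class
    targets with validity and transition flags, a transition-weighted
    multiclass cross-entropy objective for gradient boosting, a
    multinomial-regression comparator on the EDEMA score's feature set,
    a threshold-averaged one-versus-rest multiclass evaluation suite,
    Shapley feature-importance aggregation by feature category, and a
    seeded synthetic-cohort simulator so the full pipeline can be
    exercised without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    glmnet,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
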