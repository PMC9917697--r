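Package: mvscore
Title: Mitral Valve Lesion Complexity Scoring and Surgical-Approach Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying mitral valve lesion complexity from
    categorical echocardiographic features and for modelling the choice
    between mitral valve repair and replacement. Provides a weighted
    lesion complexity score with simple/intermediate/complex strata, a
    surgical technique score counting principal repair maneuvers, a
    calibrated synthetic patient cohort generator, ROC analysis of the
    complexity score with bootstrap confidence intervals and Youden
    cutoff selection, and a seeded k-fold cross-validated gradient
    boosted classifier of surgical approach with aggregated feature
    importance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
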