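Package: facekin
Title: Facial Landmark Kinematics and Ensemble Classification for
    Psychosis-Risk Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn per-frame facial-landmark trajectories (the 51
    points 17-67 of the standard 68-point annotation scheme) into robust
    per-participant kinematic summaries (eye and mouth aspect ratios, head-pose
    Euler angles, nose-anchored point angles, dispersion and autocorrelation
    statistics; 649 named features by default), to select features via
    gradient-boosting importance with pairwise product interactions, to
    classify at-risk-mental-state versus control participants with an AdaBoost
    ensemble of shallow random forests under Monte Carlo cross-validation, to
    quantify permutation feature importance, and to relate selected features to
    negative-symptom ratings with rank-sum tests. A synthetic two-group cohort
    generator with attenuated expressivity in the at-risk group makes the whole
    pipeline testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    ranger,
    xgboost,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
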