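Package: rmkpredict
Title: Predicting Discharge Upper-Limb Muscle Strength from Baseline
    Robot-Measured Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting discharge upper-limb muscle strength
    (Motricity Index) in subacute stroke from baseline planar
    robot-measured kinematic metrics.  Implements movement path error and
    mean movement speed extraction from point-to-point 2D reaching
    trajectories in a lesion-side reference frame, a synthetic cohort
    generator with controllable kinematic targets and outcome
    coefficients, least-squares outcome regression with split-sample and
    leave-one-out cross-validation, discrete clinical-score snapping, and
    the full evaluation panel (RMSE, MAE, normalized variants, R-squared,
    Spearman rank correlation with a strength rubric).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
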