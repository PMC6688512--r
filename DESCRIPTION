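Package: pdgait
Title: Gait Responsiveness Analysis for Parkinson's Disease Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline from 3D marker trajectories to spatio-temporal
    and kinematic gait parameters, speed-matched case-control comparison,
    percent-change (delta) responsiveness, anchor-based minimal clinically
    important difference (MCID) estimation via ROC cut-off analysis with
    likelihood ratios and post-test probabilities, and clinical prediction of
    gait improvement by backward-selection multiple regression. Includes a
    synthetic gait generator (marker-level forward model plus cohort-level
    clinical covariates with known regression structure) so every stage is
    testable against ground truth without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car,
    lmtest,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
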