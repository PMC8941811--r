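Package: flaretaper
Title: Dynamic Flare Prediction and Prediction-Aided Tapering of Biologic
    DMARDs in Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint latent class mixed modelling of DAS28 disease-activity
    trajectories linked to class-specific flare hazards in rheumatoid
    arthritis patients tapering biologic DMARDs.  Provides DAS28 composite
    scoring and flare detection, course assembly from visit-level tables,
    maximum-likelihood estimation with BIC model selection, landmark
    ("dynamic") prediction of 3-month flare risk, cross-validated
    discrimination and calibration metrics, a decision-rule simulator for
    prediction-aided disease-activity-guided dose optimisation, and
    synthetic cohort generators (irregular-visit EHR style and protocolised
    tapering-trial style) so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
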