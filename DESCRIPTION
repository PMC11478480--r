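Package: gaitphase
Title: Continuous Gait Phase Estimation from Insole Force-Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous gait phase estimation (cGPE) from
    plantar force-sensing-resistor (FSR) time series recorded by instrumented
    insoles. Implements a two-stage pipeline in which a walking-condition
    classifier (level walk, stair ascent/descent, ramp ascent/descent) feeds a
    continuous phase estimator; both stages are bidirectional long short-term
    memory (Bi-LSTM) networks trained on sliding windows of the ten insole
    channels. Gait phase is anchored at right heel strike, expressed on a
    0-100% cycle scale, and regressed through its sine-cosine (continuous
    sinusoidal function) encoding to remove the wrap-around discontinuity.
    Includes a stride-template simulator of multi-terrain insole recordings
    with ground-truth phase and condition labels, a plain-text recording
    format, heel-strike detection and phase labelling, stride normalisation,
    centre-of-pressure features, and evaluation metrics (circular RMSE, R2 on
    the encoded targets, rRMSE, APEE, NRMSE, confusion matrices, own- versus
    cross-subject grids, and input-feature ablations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
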