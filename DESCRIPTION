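Package: korotkoff
Title: Automatic Auscultatory Blood Pressure from Korotkoff Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic non-invasive blood pressure measurement from
    Korotkoff sounds recorded with a cuff and a stethoscope microphone.
    Detects beats from the cuff-pressure oscillation, represents each
    0.4 s sound segment as a 50-band band-pass-filtered signal stack,
    trains a probability-output residual convolutional network against a
    human-response label curve, and decides systolic and diastolic
    pressure by mean-squared-error template matching of the predicted
    probability sequence. Includes a threshold-style baseline classifier
    with the consecutive-beat decision rule, a synthetic Korotkoff-cycle
    recording generator with controllable signal-to-noise ratio for
    testing, and error-statistics utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
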