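Package: nosebandr
Title: Offset-Invariant Recognition of Cattle Chewing Behaviors from
    Noseband Pressure Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing rumination, eating, and other behaviors of
    cattle from single-channel noseband pressure sensor recordings sampled at
    50 Hz. Provides preprocessing operators that eliminate the unknown
    per-animal initial strap-on pressure (first-order difference, sliding-window
    least-squares local slope, and a sixth-order high-pass Butterworth filter
    realized as cascaded second-order sections), frequency-domain (one-sided FFT
    magnitude) and time-domain statistical feature extraction from fixed-length
    single-label windows, and a stratified k-fold cross-validation harness
    comparing gradient-boosted trees, k-nearest neighbors, support vector
    machines, and decision trees across preprocessing-by-feature pipelines.
    Includes a seeded synthetic jaw-pressure simulator producing labeled traces
    with per-animal pressure offsets, quasi-periodic chew bouts, baseline noise,
    and mechanical spike artifacts for development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    xgboost,
    e1071,
    rpart,
    caret,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
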