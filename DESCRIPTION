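Package: slrmech
Title: Recognition-Verification Mechanisms for Online Sign Language
    Recognition from sEMG and Inertial Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spotting and classifying sign-language gestures in
    continuous streams fused from 8-channel surface electromyography (sEMG)
    and a 6-channel inertial measurement unit (3-axis accelerometer plus
    3-axis gyroscope) sampled at 100 Hz. Implements a sliding-window
    recognition-verification pipeline: discrete-wavelet and piecewise
    quadratic preprocessing of raw 128-point windows, a one-dimensional
    VGG-style convolutional classifier, a Siamese verification network with
    per-class reference vectors and clamped distance thresholds for open-set
    rejection, and skip-ahead online decoding. Also provides the traditional
    segmentation-recognition baseline (energy-threshold onset detection,
    handcrafted sEMG/inertial features, RBF-SVM), a synthetic multichannel
    signal generator with annotated ground truth and non-gesture
    interference, and a five-way misrecognition taxonomy (insert,
    misalignment, repeat, substitute, delete) for scoring continuous-stream
    recognition runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
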