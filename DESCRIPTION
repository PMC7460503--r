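Package: gaitphase
Title: Gait Phase Recognition from Lower-Leg Acceleration Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the four phases of the human gait cycle (heel strike,
    flat foot, heel off, swing) from triaxial lower-leg accelerometer
    recordings using a hybrid spatiotemporal neural network (FMS-Net): a
    convolutional feature extractor feeding a long short-term memory layer,
    with a skip concatenation of the raw input vector into the fully
    connected classifier head and batch normalization throughout. Includes
    the comparison architectures (plain LSTM, LSTM+CNN, and the no-skip
    ablation), a labeled synthetic gait-signal simulator for fully
    reproducible benchmarking, and the complete evaluation calculus
    (confusion matrices, per-class and macro precision/recall/F1,
    one-vs-rest ROC and macro-AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
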