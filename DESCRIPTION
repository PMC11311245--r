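Package: m2mqus
Title: Machine-to-Machine Transfer-Function Calibration for Deep-Learning
    Quantitative Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates depth-resolved machine-to-machine (M2M) spectral
    transfer functions from calibration-phantom radio-frequency (RF)
    ultrasound acquisitions on two scanners, regularizes them with a
    Wiener-inspired signal-to-noise scheme, and applies them to move RF
    data between machine domains at train time or test time for
    convolutional tissue classifiers.  Includes a synthetic dual-machine
    RF simulator (product model of system response and tissue signal),
    depth-stratified patch extraction, polyphase sampling-rate
    conversion, a small CNN classifier harness with batch-statistics
    batch normalization, and the experiment workflows (train-time and
    test-time calibration, no-calibration variants, fine-tuning,
    AUC-threshold and BN-freezing baselines, Wilcoxon comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
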