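Package: qeyed
Title: Automated Quiet Eye Detection from Electrooculography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Quiet Eye (QE) intervals -- the final stable gaze fixation
    before a goal-directed movement -- in single-channel electrooculography
    (EOG) recorded during precision sports such as archery. Provides a seeded
    synthetic EOG simulator with ground-truth annotations, wavelet-based
    baseline-drift removal and Butterworth bandpass preprocessing, fixed-window
    segmentation with per-sample binary QE masks, augmentation and
    participant-grouped cross-validation folds, six per-sample detectors (an
    RBF-kernel support vector machine baseline and five neural sequence
    labelers: 1D CNN, Transformer, UNet, CNN-GRU and CNN-LSTM), and
    event-level evaluation that matches predicted onsets and offsets to ground
    truth under a time tolerance and reports PPV, sensitivity, F1, per-sample
    accuracy, timing biases and mean absolute error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
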