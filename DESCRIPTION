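Package: eegwave
Title: Dual-Path WaveNet-LSTM Classification of Abnormal Clinical EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic detection of abnormal clinical EEG
    recordings with a compact dual-path deep network that combines gated
    dilated causal convolutions (a modified WaveNet) with recurrent
    sequence encoders and channel-wise attention.  Includes readers and
    writers for 16-bit EDF, the clinical preprocessing pipeline
    (Butterworth and notch filtering, bipolar TCP montage derivation,
    polyphase resampling, fixed-length segmentation with time-reverse
    augmentation, per-channel standardization), a synthetic EEG generator
    with labelled spike-wave discharges and focal slowing for fully
    self-contained experiments, class-balanced training with Adam,
    plateau learning-rate decay and early stopping, and
    sensitivity/specificity/accuracy evaluation.  The network forward and
    backward passes are implemented in compiled code; no external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
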