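Package: neoseiz
Title: Neonatal EEG Seizure Detection with Fully Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end neonatal electroencephalography (EEG) seizure
    detection from weakly labelled multichannel recordings. Provides EDF
    and annotation input/output with bipolar montage derivation, a
    synthetic neonatal-like EEG simulator with controllable recording-site
    shift, band-limiting and windowing preprocessing, two fully
    convolutional one-dimensional network architectures (a compact
    baseline and an enhanced residual/depthwise/bottleneck variant with
    about 45,000 trainable parameters and a 10 s receptive field), an
    augmented training regime (dynamic amplitude rescaling, Mixup,
    weighted cross-entropy, RAdam, multi-seed ensembling), probabilistic
    postprocessing (moving-average smoothing, adaptive background
    subtraction, collar extension), epoch- and event-based evaluation
    metrics (AUC, AUC90, AUC-PR, good detection rate, false detections
    per hour), and pseudo-labelling adaptation to a new recording site.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
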