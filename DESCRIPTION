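Package: anesthnet
Title: Continuous Mean Arterial Pressure Estimation from Operating-Room Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous, causal estimation of mean arterial pressure
    (MAP) between intermittent brachial-cuff measurements, using only
    non-invasive operating-room signals: photoplethysmography (PPG), ECG,
    PPG-derived features (heart rate, perfusion index, dicrotic notch relative
    amplitude) and cuff oscillometry as calibration. Provides a seeded
    synthetic-record generator with known ground truth, pulse landmark
    detection and feature extraction, inter-cuff segmentation with a
    nine-criterion quality filter, a mechanistic Ohm-Poiseuille MAP model with
    rolling five-cuff recalibration, the AnesthNet architecture (dilated
    causal convolutional encoder fused with derived features into an LSTM
    whose initial hidden state is seeded from the latest cuff MAP), and an
    evaluation layer implementing AAMI and BHS device-validation standards,
    per-patient aggregation, a cuff-interval sweep and a latency harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    signal,
    data.table,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
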