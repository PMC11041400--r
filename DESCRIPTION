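Package: harpipe
Title: Human Activity Recognition from Smartphone Inertial Sensors
Version: 0.1.0
Authors@R:
    person("harpipe", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A trainable pipeline for classifying human activities (walking,
    jogging, sitting, standing, ascending and descending stairs) from raw
    6-channel smartphone accelerometer and gyroscope streams. Provides readers
    for CSV/JSON sensor exports, label-span annotation and sliding-window
    segmentation, per-channel normalization, sampling-rate reduction and
    sensor masking, a fixed-dimension CNN-LSTM classifier, a dimension-adaptive
    (DANA-style) classifier built around a dimension-adaptive average-pooling
    layer that tolerates varying sampling rates and sensor subsets, subject-wise
    train/test splitting, within- and cross-dataset evaluation with confusion
    matrices, a sampling-rate by sensor-subset robustness grid, and a synthetic
    IMU gait-signal generator so the full pipeline is trainable and testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    digest,
    optparse,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
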