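Package: wmconn
Title: Connectome-Based Prediction of Working-Memory Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting individual working-memory component scores
    from resting-state functional connectivity. Implements change-detection
    capacity scoring (Cowan's K, tracked K) and z-score composite construction,
    Fisher-z connectome assembly with a fixed edge-index convention,
    leave-one-out cross-validated linear support vector regression with
    within-fold weight-based feature selection at per-mille thresholds,
    permutation significance with false-discovery-rate control, network-level
    importance summaries (between-network edge strength, relative degree, node
    degree), virtual-lesion network scans, ROI percent-signal-change time
    courses, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
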