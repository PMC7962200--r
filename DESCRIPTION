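Package: hvgnet
Title: Directed Weighted Horizontal Visibility Graphs for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps EEG time series to visibility-graph networks and classifies
    emotional states from them. Implements the natural and horizontal
    visibility graphs, their forward- and backward-weighted variants whose
    edge weights are visibility angles (sums of two arctangent terms),
    four weighted-network statistics (average weighted degree, degree
    deviation, weighted clustering coefficient and its entropy), six
    time-domain amplitude features, sliding-window segmentation with
    forward/backward feature fusion and min-max normalization, and a
    cross-validated classification harness (RBF support vector machine,
    k-nearest neighbours with cross-validation-optimized hyperparameters,
    and a CART decision tree) reporting accuracy, sensitivity, specificity
    and precision. Includes a seeded generator of labelled surrogate
    multichannel EEG for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    e1071,
    methods,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
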