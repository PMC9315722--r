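Package: braingin
Title: Edge-Weighted Graph Isomorphism Networks for Functional Connectome
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification of subjects from resting-state functional
    connectomes with an edge-weighted Graph Isomorphism Network (GIN).
    Builds Fisher-z functional-connectivity matrices from ROI time series,
    thresholds them into sparse weighted brain graphs, trains a GIN with
    per-layer gated attention pooling under stratified k-fold
    cross-validation, reports accuracy, precision, recall, specificity and
    F1, and consolidates the learned node attention into salient-ROI sets
    with seven-network summaries. Includes a synthetic cohort generator
    with planted discriminative subnetworks and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
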