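Package: wheatstage
Title: Multi-Scale Attention Networks for Wheat Growth-Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying wheat phenological growth stages
    (Tillering, Mid Vegetative, Booting, Heading, Milking) from ground-level
    RGB field imagery. Implements a multi-scale convolutional network with an
    adaptive multi-scale attention fusion head: a ResNet-101-style backbone
    feeds a cross-scale interaction block (global-context channel and spatial
    attention plus per-scale transformer refinement) and a confidence-weighted
    feature aggregation stage. Includes metadata filtering by label quality,
    stratified splitting, a geometric and photometric augmentation pipeline,
    a synthetic field-image generator with trapezoidal region-of-interest
    masking, a full one-vs-rest evaluation battery (confusion matrix, Top-1,
    precision, recall, F1, ROC-AUC with micro, macro and weighted averaging),
    an AdamW training loop with plateau learning-rate decay and early
    stopping, parameter audits against the published architecture table, and
    a command-line interface. The neural-network layers and reverse-mode
    gradients are implemented in R and C++ on top of BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jpeg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
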