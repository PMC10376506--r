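Package: wingmark
Title: Heatmap-Based Landmark Detection for Insect Wing Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects homologous landmarks on insect wing images with a
    multi-resolution convolutional network trained by Gaussian heatmap
    regression. Provides readers and writers for COCO-dialect keypoint
    annotations of wing datasets, a Gaussian heatmap encoder/decoder with
    sub-pixel refinement, a four-stage high-resolution backbone with
    parallel multi-resolution branches and feature fusion, transfer-learning
    strategies that freeze or retrain individual network stages, an Adam
    training loop with a stepped learning-rate schedule, normalized mean
    error (NME) evaluation against a specimen-specific reference distance,
    and a procedural generator of synthetic wing images with exact
    ground-truth landmarks for testing the full pipeline on a desktop CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
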