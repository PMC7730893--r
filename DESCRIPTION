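Package: plumvision
Title: Multi-Defect Classification of Green Plums from RGB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for grading green plums (Prunus mume) by
    surface condition from single-fruit RGB photographs. Provides a
    deterministic background-cropping preprocessor (Gaussian smoothing,
    adaptive thresholding, Laplacian filtering, Canny edge extraction and
    minimal bounding rectangle), severity-priority labelling with a tenfold
    mirror/rotation augmentation scheme, a 16-weight-layer VGG-style
    convolutional network with batch normalization and adaptive average
    pooling, a negative-focused weight-biased softmax (w-softmax) loss,
    stochastic weight averaging (SWA) on a cyclic learning rate, a
    procedural generator of plum-like images with class-specific defect
    morphologies, and a confusion-matrix evaluation suite with per-class
    precision, recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
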