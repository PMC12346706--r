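Package: dermbag
Title: Edge- and Color-Texture-Aware Bag-of-Local-Features Models for Skin Lesion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bag-of-local-features classification of dermoscopy-style skin lesion
    images with strictly limited receptive fields. A convolutional backbone maps a
    225x225 image to a 25x25x2048 grid of local features, each depending on exactly
    one 33x33 patch (stride 8). Training couples classification with non-rigid
    reconstruction of two handcrafted targets, a 354-dimensional uniform local
    binary pattern color-texture descriptor over RGB and YUV channels and a Sobel
    edge map, through reparameterized Gaussian sampling and a damped
    Kullback-Leibler reconstruction loss. Includes sharpness-aware minimization and
    its partial variant, per-patch interpretable heatmaps (color-texture, edge, and
    overall), heatmap-guided occlusion analyses, a synthetic lesion image generator
    with controllable boundary-sharpness and mottling cues, and command-line entry
    points. The convolutional engine (no-padding convolutions, transposed
    convolutions, batch normalization, backpropagation) is implemented in-package
    on top of Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff
Config/testthat/edition: 3
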