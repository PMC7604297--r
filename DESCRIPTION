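Package: rootseg
Title: Root Segmentation for Minirhizotron Images with Sub-Pixel Upsampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of plant roots in minirhizotron soil-profile
    scans. Implements an encoder-decoder convolutional network with atrous
    spatial pyramid pooling (output stride 16) whose final 4x upsampling stage
    is interchangeable between bilinear interpolation and learned sub-pixel
    convolution (PixelShuffle), a pad/tile/stitch pipeline so gigapixel scans
    fit a fixed 512x512 network input, a seeded synthetic root-scene generator
    with exact ground-truth masks, a pixel-wise cross-entropy/Adam training
    loop, and pixel-level precision/recall/F1/dice evaluation with micro and
    macro aggregation. All numerics are implemented in R/C++ on BLAS; no
    external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
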