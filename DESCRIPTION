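Package: texbound
Title: Class-Independent Texture Boundary Detection with an
    Encoder-Decoder Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects boundaries between texture regions in images without
    a predefined set of texture classes, by classifying every pixel as
    either border or interior with a small fully convolutional
    encoder-decoder network trained on procedurally assembled texture
    mosaics. Provides the mosaic generators (Voronoi, random-walk and
    circular structures) with border-band ground truth, the per-texture
    augmentation chain, CPU training of the network with binary
    cross-entropy and Adam, and the edge-map evaluation protocol:
    precision-recall curves and their area, F-measure, and the Pratt
    Figure of Merit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
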