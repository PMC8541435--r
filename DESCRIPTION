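Package: cimtseg
Title: Carotid Intima-Media Complex Segmentation and Thickness Measurement
Version: 0.1.0
Authors@R:
    person("cimtseg", "maintainers", email = "cimtseg@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for segmenting the intima-media complex (IMC)
    in longitudinal B-mode carotid ultrasound images and estimating carotid
    intima-media thickness (cIMT). Includes a synthetic speckle-phantom
    generator with known band geometry, Sobel/Prewitt gradient-direction
    preprocessing, a dual-encoder convolutional encoder-decoder trained with
    pixel-wise cross-entropy, morphological mask refinement, column-run
    thickness measurement with pixel-to-millimetre calibration, and
    segmentation metrics (precision, recall, F1, Dice, Jaccard) with macro and
    micro averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
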