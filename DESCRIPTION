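Package: polypseg
Title: Polyp Segmentation with a Harmonic Dense Encoder and Spatial-Channel Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An encoder-decoder network for segmenting colorectal polyps in
    endoscopy images, built around a HarDNet68 harmonic dense-block encoder, a
    densely connected atrous spatial pyramid pooling (DenseASPP) bridge, and a
    decoder whose stages apply a combined spatial and channel attention (SCA)
    module. Includes the compound Dice plus focal training objective, the six
    standard segmentation evaluation measures (mDice, mIoU, sensitivity,
    specificity, structure measure, MAE), paired image/mask augmentation and
    dataset splitting, a synthetic endoscopy-image generator for end-to-end
    testing without external data, and a CPU training engine with Adam
    optimization and early stopping. All tensor operations (convolution,
    pooling, bilinear resampling, batch normalization) are implemented with a
    small reverse-mode automatic differentiation tape backed by compiled
    kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    png,
    yaml,
    jsonlite,
    EBImage,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
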