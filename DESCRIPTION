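Package: lftmri
Title: Linear Fine-Tuning Transfer Strategies for Deep MRI Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter-efficient transfer learning for convolutional MRI
    reconstruction networks. Implements linear fine-tuning (LFT), in which a
    pre-trained network is adapted to a new imaging domain by learning one
    scaling and one shifting factor per convolution kernel while the
    pre-trained weights and biases stay frozen, alongside the conventional
    comparison strategies (direct testing, training from scratch, full
    fine-tuning, and row-wise fine-tuning). Ships a retrospective Cartesian
    k-space undersampling forward model with variable-density row masks,
    zero-filled reconstruction, PSNR/SSIM/weighted-PSNR image-quality
    metrics, a compact residual U-net reconstruction generator trained on
    the CPU, and a synthetic phantom generator that emulates domain shifts
    in contrast, slice orientation, and anatomy so every transfer scenario
    is exercisable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
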