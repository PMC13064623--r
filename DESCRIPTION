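Package: stedgan
Title: Lightweight Adversarial Modality Transfer for Confocal-to-STED Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-modality image translation for fluorescence microscopy:
    Pix2Pix and CycleGAN training with a registry of nine U-Net generator
    variants spanning the conventional channel-doubling design and a
    lightweight fixed-channel design, a PatchGAN discriminator, and the full
    surrounding pipeline. Includes a synthetic confocal/STED/deconvolved-STED
    phantom generator for cilium-like structures, ImageJ-style preprocessing
    (contrast stretch, Otsu segmentation and cropping, zero padding, dihedral
    augmentation), reference and non-reference image-quality metrics (SSIM,
    PSNR, normalized PSNR, Fourier ring correlation, line profiles, SNR, edge
    preservation, deviation maps), and an evaluation harness with k-fold
    cross-validation, repeated-measures ANOVA and Holm-corrected pairwise
    tests. The convolutional network core (convolutions, transposed
    convolutions, instance normalization, Adam) is implemented in
    C++ via Rcpp/RcppArmadillo and runs on the CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
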