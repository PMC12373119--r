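Package: organoColor
Title: Conditional-GAN Fluorescence Colorization of Cardiac Organoid
    Phase-Contrast Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Virtual fluorescence staining for human pluripotent stem
    cell derived cardiac organoids. A conditional generative adversarial
    network (U-Net generator with convolutional block attention, patch
    discriminator) learns to predict the chromatic a*/b* CIELAB channels
    of a two-reporter fluorescence image (GFP cardiomyocytes, mOrange
    endothelial cells) from the Lightness channel of the paired
    phase-contrast image. Includes the exact sRGB/CIELAB conversion
    chain, adversarial plus L1 training with model variants and
    fine-tuning for new differentiation batches, the PSNR, SSIM and
    weighted patch histogram (WPH) evaluation metrics, per-channel
    fluorescence quantification, and a procedural generator of paired
    synthetic organoid images with ground-truth cell-type masks. All
    network layers and their backward passes are implemented in the
    package (Rcpp/RcppArmadillo kernels); no external deep-learning
    framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, png, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
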