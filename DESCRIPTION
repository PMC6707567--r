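Package: rdaunet
Title: Residual-Dilated-Attention U-Net for Breast Ultrasound Lesion
    Segmentation
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encoder-decoder semantic segmentation of breast ultrasound
    (B-mode) lesions with the RDAU-NET architecture: residual convolution
    units, a six-branch dilated-convolution bridge enlarging the receptive
    field at the bottleneck, and attention-gated skip connections that
    suppress background responses. Includes a self-contained numerical
    engine (compiled convolution forward/backward passes, batch
    normalisation, Adam, soft-Dice training), the nine-score evaluation
    battery (Dice, accuracy, sensitivity, specificity, F1, precision, mean
    IOU, ROC/PR AUC), paired affine data augmentation, a seeded synthetic
    ultrasound-phantom generator with speckle noise, and a command-line
    pipeline for training, evaluation and prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
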