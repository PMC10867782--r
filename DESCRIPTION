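Package: tsegan
Title: Conditional Adversarial Synthesis of Thyroid Strain Elastograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates grayscale B-mode thyroid ultrasound images into color
    strain-elastography images with a conditional generative adversarial
    network. The generator combines a deformable-convolution local branch on a
    nodule region of interest, a global branch with spatial attention, a
    spatially-adaptive denormalization (SPADE) decoder and an attention-based
    content revisor; two conditional PatchGAN discriminators drive an
    objective of adversarial, feature-matching and blurred CIELAB color
    losses. Includes a seeded synthetic phantom generator producing paired
    B-mode/elastogram images with known Rago-style stiffness scores, a CPU
    training loop with two-time-scale Adam updates, image-quality metrics
    (PSNR, SSIM, MSE), a blue/green-ratio stiffness scorer, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    EBImage,
    grDevices,
    stats,
    utils,
    tools,
    optparse,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
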