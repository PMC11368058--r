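Package: pseudohealthy
Title: Three-Stage Pseudo-Healthy Synthesis for Lesioned Brain Image Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inpainting-based pseudo-healthy synthesis for 2-D brain image
    slices. A pluggable segmentor localizes lesions, a gated-convolution
    coarse filler reconstructs a blurry healthy outline of the lesion region
    plus a 5 mm margin, and a flip-symmetric refinement generator with
    contextual residual attention transplants high-frequency texture from
    healthy context (including the contralateral hemisphere) into the filled
    region. Training uses healthy slices with random 30-60% masks, an L1
    objective for the coarse filler, and hinge adversarial plus perceptual
    objectives for the refinement generator. Includes a synthetic brain
    phantom generator with mass-effect lesions, and an evaluation suite:
    healthiness, masked PSNR/SSIM identity metrics, and structure
    healthiness from a binary classifier on Canny edge maps. All trainable
    stages run on a compact deterministic CPU conv-net engine included in
    the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    RNifti,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'pseudohealthy-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'image_core.R'
    'io.R'
    'nn.R'
    'phantoms.R'
    'unet.R'
    'segmentor.R'
    'vague_filler.R'
    'attention.R'
    'generator.R'
    'adversarial.R'
    'pipelines.R'
    'canny.R'
    'ssim.R'
    'metrics.R'
    'edge_classifier.R'
    'config.R'
    'cli.R'
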