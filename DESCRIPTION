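Package: dbtgan
Title: CycleGAN Pre-Reconstruction Processing and Image-Quality Evaluation
    for Digital Breast Tomosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale toolkit for limited-angle digital breast tomosynthesis
    (DBT). Simulates synthetic breast phantoms and dose-dependent projection
    acquisition (exposure/deviation indices), performs unpaired low-dose to
    reference-dose projection translation with a cycle-consistent generative
    adversarial network whose generator augments a residual U-Net with a
    squeeze-and-excitation bridge and attention-gated skip connections
    (rSEAG), reconstructs slices by shift-and-add filtered backprojection
    with the Ramachandran-Lakshminarayanan ramp kernel, and evaluates
    reconstructions with a PIQE-style no-reference block-distortion score,
    grey-level co-occurrence texture features (homogeneity, contrast) and a
    Gumbel extreme-value statistic of streak artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
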