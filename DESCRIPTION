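Package: sialoquant
Title: Quantitative Salivary Gland SPECT/CT with Automated Gland Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for quantitative Tc-99m pertechnetate salivary gland
    SPECT/CT. Generates synthetic head-and-neck CT/SPECT phantoms with known
    gland uptake kinetics, crops CT volumes to a fixed training matrix using
    soft-tissue profiles, trains a configurable 3D U-Net to segment the
    parotid and submandibular glands, corrects rigid SPECT-CT misregistration
    by normalized cross-correlation, computes per-gland percent injected dose
    (%ID) and percent excretion fraction (%EF) from voxel-of-interest sums,
    accounts protocol radiation dose, and provides the agreement statistics
    (Dice, ICC, Bland-Altman, MAPE, R squared, paired t) used to validate
    automated against manual segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
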