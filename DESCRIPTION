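Package: segqa
Title: Uncertainty-Aware Quality Assurance for Multi-Class Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reliability of multi-class image
    segmentations with Monte Carlo dropout. Provides a synthetic phantom
    generator for pelvic-like four-class segmentation problems (background,
    target, bladder, rectum) with in-distribution and out-of-distribution
    cohorts, a small trainable 2D U-Net with learnable spatial concrete
    dropout, Monte Carlo ensemble inference, predictive-entropy and
    mutual-information uncertainty maps, pixel-outcome stratification with
    certain/uncertain grouped Dice analysis, standard geometry metrics
    (Dice, HD95, mean surface distance), scan-level out-of-distribution
    scoring, and uncertainty-map visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    EBImage,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
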