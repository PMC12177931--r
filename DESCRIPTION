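Package: patternoid
Title: Morphometrics and Dose-Response Analysis for Microcavity-Array
    Organoid Invasion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies invasive phenotypes of organoids ("patternoids") grown
    in collagen microcavity arrays. Provides the physical array geometry and
    pixel calibration, a synthetic-data generator producing binary invasion
    masks with known ground truth, the z-projection/denoise/binarize image
    pipeline, skeleton-based morphometrics (invasive and non-invasive area,
    maximum invasive distance, invasive roots and tips, branching factor),
    starting-cell-number cohort control and pooling, time-resolved ROI
    quantification with linear mixed-effects trend testing, and Hill
    dose-response fitting with EC50 extraction for protease-inhibitor assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    lmerTest,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
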