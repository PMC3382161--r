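Package: roundtrack
Title: Shape-Based Tracking and Classification of Motile Immune Cells in Two-Photon Lung Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel time-lapse two-photon movies of
    lung tissue: rigid drift correction by maximizing the normalized spatial
    cross-correlation of the structural second-harmonic (collagen) channel,
    segmentation of fluorescent cells with per-frame circularity (Instantaneous
    Roundness Coefficient) scoring, multiple-particle track linking, per-track
    motility metrics (mean roundness, maximal distance, meandering index,
    velocity), discrimination of dendritic-shaped versus round-shaped cells by
    a double-Gaussian fit of the mean-roundness distribution, and Mann-Whitney
    group comparisons. Includes a synthetic movie generator with exported
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
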