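Package: neutroscope
Title: Neutrophil Quantification and Calibration Tools for High-Throughput
    Light-Sheet Microscopy of Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for automated light-sheet fluorescence
    microscopy of larval zebrafish: 3D segmentation of GFP-labelled
    neutrophils by coarse thresholding, morphological cleaning and iterated
    per-object Otsu refinement; specimen fine-positioning by 1D brightfield
    intensity-profile registration (cross-correlation and minimum-location
    methods) against a template library; point-spread-function estimation
    from fluorescent bead stacks by Gaussian line-scan fitting; cohort-level
    statistics of neutrophil counts and fluorescence; and seeded synthetic
    generators (blob stacks, bead stacks, brightfield profiles, cohort
    tables) providing ground truth for every stage. Includes a minimal
    multi-page TIFF reader/writer with voxel-spacing metadata and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
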