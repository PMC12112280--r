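Package: vesselect
Title: Uniform Feature-Space Sample Selection for Vessel Image Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating heterogeneous subsets of large unannotated
    vessel-microscopy image collections for manual annotation. Maps image
    patches to a four-dimensional morphometry feature space (vessel contrast,
    wavelet-estimated Gaussian noise, skeleton density, and detrended medial-line
    intensity heterogeneity), discretizes the space on a regular grid, builds a
    union-of-hyperspheres sampling set, and selects samples that cover the space
    uniformly by minimizing the farthest-unselected-point (FUS) statistic.
    Includes a synthetic tubular-image generator with known ground-truth
    properties, patch extraction and filtering, distribution-shift split
    generation, and topology-aware segmentation metrics (Dice, centerline Dice,
    smoothed train/validation loss gaps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
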