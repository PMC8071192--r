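Package: cmre
Title: Compression MR Elastography of Tumors: Simulation, Reconstruction
    and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for assessing tumor biomechanics with magnetic
    resonance elastography (MRE) under graded compression. Simulates wrapped-phase
    shear-wave acquisitions in viscoelastic tumors, reconstructs per-voxel storage
    and loss moduli by phase unwrapping, harmonic extraction, curl and Helmholtz
    inversion, derives the compression stiffening rate (slope of elasticity versus
    applied compression), quantifies collagen fraction and cellularity from
    synthetic histology tiles, and runs the cohort statistics used in small-animal
    tumor studies: Mann-Whitney comparisons, partial correlations with tumor type
    as covariate, stepwise multiple regression, rank-based ROC analysis with
    Hanley-McNeil standard errors, and AUC-based sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
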