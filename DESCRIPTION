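Package: cryoclear
Title: Cryomicrotome Imaging Analysis of Solute Clearance from the Mouse
    Hippocampus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for episcopic fluorescence
    cryomicrotome studies of tracer clearance from the mouse brain. Provides
    a synthetic phantom generator (stylized labeled mouse anatomy, explicit
    finite-difference tracer transport, slice-image rendering with camera
    artifacts), slice pre-processing (stuck-pixel repair, isotropic block-mean
    reconstruction), fixed-threshold segmentation with voxel volumetry and
    isosurface meshing, per-structure presence scoring, and the study-level
    statistics: a from-scratch binary generalized estimating equation with
    exchangeable working correlation and cluster-robust errors, and an exact
    permutation Mann-Whitney U test for small samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    RNifti,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
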