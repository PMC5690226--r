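Package: deformgen
Title: Population-Learned Deformation Models for Validating Deformable
    Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns statistical (active shape) models of inter- and
    intra-patient anatomical variation from deformation vector fields,
    samples Mahalanobis-bounded random deformations from them, and
    generates artificial planning/daily CT image pairs with voxel-level
    ground-truth deformation for validating deformable image registration
    (DIR).  Includes a demons-family deformable registration engine, DVF
    algebra (iterative inversion, composition, cross-space transfer),
    NIfTI and MetaImage I/O for volumes and vector fields, a synthetic
    head-and-neck phantom population generator with known ground truth,
    and voxel- and contour-level validation metrics (registration error
    maps, Dice, mean surface distance, mode-coverage analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
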