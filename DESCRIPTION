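Package: vesselmorph
Title: Morphological Quantification of Cerebrovascular Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the morphology of brain blood vessels from 3D binary
    segmentation masks in NIfTI format. Reduces a vessel mask to a one-voxel-wide
    centerline by topology-preserving 3D thinning, classifies centerline voxels
    into endpoints, regular points and bifurcations, estimates per-point vessel
    radii from an anisotropic Euclidean distance transform, decomposes the
    centerline into bifurcation-to-bifurcation vessel segments, and summarises
    length, chord, tortuosity, radius and volume into a per-subject feature
    vector in physical units (mm). Includes the Dice overlap metric, a synthetic
    vascular-phantom generator with analytic ground truth, and the statistical
    evaluation protocol used for relating vessel features to age, blood
    pressure, cognition and hypertension: ordinary least-squares and logistic
    model fitting, nested-model analysis of variance, and k-fold cross-validated
    coefficients of determination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
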