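Package: tpmars
Title: Spline-Based Construction of MRI Tissue Probability Map Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds demographic-specific brain MRI tissue priors by fitting
    multivariate adaptive regression splines (MARS) voxelwise to cohorts of
    spatially normalized tissue probability maps. Models age, sex, scanner
    field strength and a combined data-quality indicator; supports four
    homogeneity-enforcement options from a fully global to a fully
    independent per-voxel fit; generates six-class tissue priors for
    arbitrary in-range demographic targets ("matched pairs" averaging, 3D
    median filtering, six-class consistency); and implements the
    accompanying quality-control metrics (affine and Jacobian volume-change
    summaries, dissimilarity from the cohort mean, 26-neighborhood
    inhomogeneity, polynomial GLM and moving-average baselines, and the
    prior-versus-average comparison protocol). A seeded phantom-cohort
    generator with known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
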