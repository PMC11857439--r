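Package: striatnorm
Title: Normative Modeling of Age-Related Striatal Glucose Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how striatal glucose metabolism changes with
    age in FDG-PET: band-based intensity normalization and atlas ROI
    extraction for spatially aligned volumes, Pearson age correlations with
    Bonferroni correction, mass-univariate voxel-wise regression with
    max-statistic permutation family-wise-error control and cluster-extent
    reporting, and a warped (sinh-arcsinh) Bayesian linear-regression
    normative model of regional uptake with B-spline age trajectories,
    centile curves, deviation Z-scores and explained-variance evaluation.
    Includes a calibrated synthetic-cohort generator so the full pipeline is
    testable without imaging downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
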