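Package: nlmorph
Title: Mass-Univariate Nonlinear Morphometry for Brain Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise and vertexwise modeling of linear and nonlinear
    covariate effects on structural brain images. Covariates are split into
    confounders (correctors) and variables of interest (predictors) through a
    contrast matrix; models are fitted in two stages (correctors first,
    predictors on the residuals) using multiple linear regression with
    polynomial expansion, additive models estimated by backfitting, or
    epsilon-insensitive support vector regression with kernels. Per-location
    goodness-of-fit and complexity metrics (MSE, R-squared, AIC, nested-model
    F-test, roughness-penalized residual sum of squares) yield statistical
    maps; post-hoc tools combine maps across models and cluster fitted curves
    with a derivative-weighted distance. Includes readers and writers for
    NIfTI, MGH and FreeSurfer curvature formats, a synthetic phantom
    generator with known ground-truth curve families, and a staged,
    configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    cluster,
    MASS,
    readxl,
    withr
Config/testthat/edition: 3
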