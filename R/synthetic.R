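#' Specify a synthetic phantom
#'
#' Defines a reproducible imaging phantom with known ground truth, mimicking
#' the structure of a morphometry study along a disease-staging axis: a
#' scalar disease index (uniform on \[0, 2\]) acts as the predictor, while
#' age (uniform on \[45, 75\]) and sex (Bernoulli 1/2) act as correctors with
#' linear, quadratic and offset effects. Disjoint voxel regions carry one
#' ground-truth curve family each — `"null"`, `"linear"`, `"quadratic"` or
#' `"sigmoid"` (parameterized `a / (1 + exp(-b (x - c)))`, a saturating
#' nonlinear trajectory) — on top of i.i.d. Gaussian noise.
#'
#' The defaults (16^3 volume, L = 80 subjects, effect sizes around 0.3-0.5
#' against noise sigma 0.4) give a moderate signal-to-noise regime: strong
#' enough for stable F-tests, small enough that linear and nonlinear models
#' are genuinely distinguishable.
#'
#' @param L Number of subjects.
#' @param shape Volume dimensions.
#' @param regions A list of regions, each `list(voxels = , family = ,
#'   effect = )` with `voxels` an n x 3 matrix of 1-based voxel
#'   coordinates; `NULL` for the default three 3x3x3 regions (linear,
#'   quadratic, sigmoid).
#' @param corrector_effects Named list: `age_slope`, `age2`, `sex`.
#' @param baseline Constant tissue-intensity offset.
#' @param sigma Noise standard deviation (`>= 0`).
#' @param seed Integer seed; fixed seed implies bit-identical phantoms.
#' @return An object of class `nm_phantom_spec`.
#' @export
phantom_spec <- function(L = 80, shape = c(16, 16, 16), regions = NULL,
                         corrector_effects = list(age_slope = -0.01,
                                                  age2 = -5e-4, sex = 0.05),
                         baseline = 1, sigma = 0.4, seed = 42) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (is.null(regions)) {
    # three 3x3x3 cubes at shape-relative positions, so smaller test volumes
    # carry the same structure
    lo <- pmax(floor(shape * 0.2), 1)
    hi <- pmin(floor(shape * 0.6) + 1, shape - 2)
    cube <- function(o) as.matrix(expand.grid(o[1] + 0:2, o[2] + 0:2, o[3] + 0:2))
    regions <- list(
      list(voxels = cube(c(lo[1], lo[2], lo[3])), family = "linear", effect = -0.3),
      list(voxels = cube(c(hi[1], lo[2], lo[3])), family = "quadratic", effect = -0.3),
      list(voxels = cube(c(lo[1], hi[2], hi[3])), family = "sigmoid", effect = -0.5)
    )
  }
  lin <- lapply(regions, function(r) {
    v <- as.matrix(r$voxels)
    if (any(v < 1) || any(sweep(v, 2, shape, `>`))) abort("region voxels outside the volume")
    v[, 1] + (v[, 2] - 1) * shape[1] + (v[, 3] - 1) * shape[1] * shape[2]
  })
  if (anyDuplicated(unlist(lin))) abort("regions overlap")
  structure(list(L = L, shape = shape, regions = regions,
                 region_index = lin,
                 corrector_effects = corrector_effects, baseline = baseline,
                 sigma = sigma, seed = seed),
            class = "nm_phantom_spec")
}

# Ground-truth curve families on the disease-index axis x in [0, 2].
truth_curve <- function(family, effect, x) {
  switch(family,
    null = rep(0, length(x)),
    linear = effect * x,
    quadratic = effect * x^2,
    sigmoid = effect / (1 + exp(-6 * (x - 1))),
    abort(sprintf("unknown curve family '%s'", family)))
}

#' Generate a synthetic phantom
#'
#' Draws covariates and per-subject volumes according to a
#' [phantom_spec()]: voxel value = baseline + region curve(disease index) +
#' age, age-squared and sex corrector effects + Gaussian noise. With
#' `dir` given, subject volumes (uncompressed NIfTI), the covariate table
#' (CSV), the ground-truth curves (CSV) and a manifest (JSON) are written
#' to disk; the same objects are always returned in memory.
#'
#' @param spec An `nm_phantom_spec`.
#' @param dir Optional output directory.
#' @return A list: `obs` (an `nm_obs`), `covariates` (tibble with columns
#'   `adcsf`, `age`, `sex`), `truth` (tibble of ground-truth curves on a
#'   100-point grid), `region_index` (list of linear voxel indices per
#'   region), `files` (paths, when written).
#' @export
generate_phantom <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "nm_phantom_spec"))
  set.seed(spec$seed)
  L <- spec$L
  covariates <- tibble(
    adcsf = runif(L, 0, 2),
    age = runif(L, 45, 75),
    sex = rbinom(L, 1, 0.5)
  )
  N <- prod(spec$shape)
  ce <- spec$corrector_effects
  corr <- spec$baseline + ce$age_slope * covariates$age +
    ce$age2 * covariates$age^2 + ce$sex * covariates$sex
  data <- matrix(corr, L, N)
  for (k in seq_along(spec$regions)) {
    r <- spec$regions[[k]]
    sig <- truth_curve(r$family, r$effect, covariates$adcsf)
    data[, spec$region_index[[k]]] <- data[, spec$region_index[[k]]] + sig
  }
  if (spec$sigma > 0) data <- data + matrix(rnorm(L * N, 0, spec$sigma), L, N)

  grid <- seq(0, 2, length.out = 100)
  truth <- purrr::map_dfr(seq_along(spec$regions), function(k) {
    r <- spec$regions[[k]]
    tibble(region = k, family = r$family, grid = grid,
           value = truth_curve(r$family, r$effect, grid))
  })

  geometry <- list(type = "volume", dim = spec$shape, affine = diag(4),
                   format = "nii", template = NULL, n = N)
  obs <- structure(list(data = data, mask = apply(data, 2, var) > 0,
                        geometry = geometry, paths = NULL),
                   class = "nm_obs")
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    img_paths <- file.path(dir, sprintf("subject_%03d.nii", seq_len(L)))
    for (i in seq_len(L)) {
      write_image(array(data[i, ], dim = spec$shape), img_paths[i], geometry)
    }
    cov_path <- file.path(dir, "covariates.csv")
    write.csv(covariates, cov_path, row.names = FALSE)
    truth_path <- file.path(dir, "ground_truth_curves.csv")
    write.csv(truth, truth_path, row.names = FALSE)
    manifest <- list(
      L = L, shape = spec$shape, sigma = spec$sigma, seed = spec$seed,
      regions = lapply(seq_along(spec$regions), function(k) list(
        family = spec$regions[[k]]$family,
        effect = spec$regions[[k]]$effect,
        n_voxels = nrow(spec$regions[[k]]$voxels))),
      images = basename(img_paths), covariates = basename(cov_path))
    jsonlite::write_json(manifest, file.path(dir, "phantom_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list(images = img_paths, covariates = cov_path,
                  truth = truth_path,
                  manifest = file.path(dir, "phantom_manifest.json"))
    obs$paths <- img_paths
  }
  list(obs = obs, covariates = covariates, truth = truth,
       region_index = spec$region_index, files = files)
}

#' Generate a labeled set of synthetic curves
#'
#' Fixture generator for curve clustering: draws `n_per_family` curves per
#' family on the standard 100-point grid over \[0, 2\], with mild random
#' variation of the family parameters plus i.i.d. Gaussian perturbations,
#' and returns the true family labels.
#'
#' @param families Character vector from `"null"`, `"linear"`,
#'   `"quadratic"`, `"sigmoid"`.
#' @param n_per_family Curves per family (`>= 1`).
#' @param noise Standard deviation of the pointwise perturbation.
#' @param seed Integer seed.
#' @param T Grid size.
#' @return A list: `curves` (an `nm_curves`), `labels` (integer vector,
#'   indexing `families`).
#' @export
generate_curve_set <- function(families = c("linear", "sigmoid"),
                               n_per_family = 20, noise = 0.05, seed = 1,
                               T = 100) {
  stopifnot(n_per_family >= 1)
  set.seed(seed)
  grid <- seq(0, 2, length.out = T)
  # three distinct trajectory archetypes: rising line, accelerating decline,
  # steep saturating S-curve; mutually well separated under the
  # derivative-weighted distance
  base_effect <- c(null = 0, linear = 0.5, quadratic = -0.5, sigmoid = 3)
  rows <- list(); labels <- integer(0)
  for (k in seq_along(families)) {
    fam <- families[k]
    for (i in seq_len(n_per_family)) {
      eff <- base_effect[[fam]] * (1 + runif(1, -0.15, 0.15))
      y <- truth_curve(fam, eff, grid) + rnorm(T, 0, noise)
      rows[[length(rows) + 1]] <- y
      labels <- c(labels, k)
    }
  }
  curves <- do.call(rbind, rows)
  list(curves = new_curve_set(grid, curves), labels = labels)
}
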