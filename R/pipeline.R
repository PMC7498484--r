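#' Default pipeline configuration
#'
#' The analysis pipeline is driven by a configuration list (storable as
#' YAML) and split into stages run by [run_stage()]. The default
#' configuration documents every knob: input paths, covariate
#' preprocessing, the contrast (or, more simply, predictor column names),
#' one or more named models (corrector and predictor fitter specs),
#' inference metrics and thresholds, comparison and clustering settings,
#' chunk size and seed.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    paths = list(covariates = NULL, images = NULL, mask = NULL,
                 output = "nlmorph_output"),
    preprocessing = "none",
    predictors = "adcsf",
    contrast = NULL,                  # M x P matrix (list of rows) overrides predictors
    sigma_min = 0,
    models = list(
      # correctors in covariate-file order (age, sex): quadratic age, sex
      glm1 = list(corrector = list(family = "glm", degrees = c(2, 1)),
                  predictor = list(family = "glm", degrees = 1)),
      glm2 = list(corrector = list(family = "glm", degrees = c(2, 1)),
                  predictor = list(family = "glm", degrees = 2))
    ),
    inference = list(metrics = c("ftest", "mse", "r2"), gamma = 1,
                     threshold = 0.001, cluster_extent = 1,
                     adjust = "none", curve_grid = 100),
    compare = list(kind = "best", models = NULL, metric = "ftest"),
    clustering = list(model = NULL, metric = "ftest", threshold = 0.001,
                      cluster_extent = 1, n_clusters = 2,
                      weights = c(0.2, 0.8, 0.2), standardize = TRUE),
    show_curves = list(coordinate = NULL, models = NULL),
    phantom = list(L = 80, shape = c(16, 16, 16), sigma = 0.4, seed = 42),
    chunk_size = 512,
    seed = 1
  )
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over
#' [default_config()]; unspecified keys keep their defaults.
#'
#' @param path YAML/JSON file path, or a list already in memory.
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else {
    ext <- tolower(tools::file_ext(path))
    if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])) && nm != "models") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

apply_overrides <- function(config, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    config <- set_nested(config, parts, overrides[[key]])
  }
  config
}

set_nested <- function(x, parts, value) {
  if (length(parts) == 1) {
    x[[parts]] <- value
  } else {
    x[[parts[1]]] <- set_nested(x[[parts[1]]] %||% list(), parts[-1], value)
  }
  x
}

# Turn a config fitter description into an nm_fitter_spec.
parse_fitter_spec <- function(cfg) {
  if (inherits(cfg, "nm_fitter_spec")) return(cfg)
  if (is.null(cfg)) return(spec_glm(1))
  switch(cfg$family,
    glm = spec_glm(unlist(cfg$degrees) %||% 1),
    gam = {
      sms <- lapply(cfg$smoothers %||% list(list(kind = "bspline", df = 8)),
                    function(s) switch(s$kind,
                      linear = sm_linear(),
                      poly = sm_poly(s$degree),
                      bspline = sm_bspline(s$df),
                      nspline = sm_nspline(s$df),
                      abort(sprintf("unknown smoother kind '%s'", s$kind))))
      spec_gam(sms, max_iter = cfg$max_iter %||% 500, tol = cfg$tol %||% 1e-6)
    },
    svr = spec_svr(kernel = cfg$kernel %||% "rbf", eps = cfg$eps %||% 0.1,
                   cost = cfg$cost %||% 1, gamma = cfg$gamma %||% 1,
                   degree = cfg$degree %||% 3, coef0 = cfg$coef0 %||% 1),
    abort(sprintf("unknown fitter family '%s'", cfg$family)))
}

#' Run one pipeline stage
#'
#' Executes one step of the staged analysis: `"generate-phantom"`, `"fit"`,
#' `"infer"`, `"compare"`, `"cluster"`, `"show-curves"` or
#' `"show-data-distribution"`. Each stage writes its artifacts plus a
#' manifest under the configured output directory, checks that the
#' manifests of its prerequisite stages exist (telling you which stage to
#' run first otherwise), echoes the effective configuration, and appends to
#' a run log. Re-running a stage overwrites only its own artifacts.
#'
#' @param stage Stage name.
#' @param config A configuration list, or a path to a YAML/JSON file (see
#'   [load_config()]).
#' @param overrides Named list of configuration overrides with dotted keys,
#'   e.g. `list("inference.threshold" = 0.01)`.
#' @return Invisibly, a list of the artifacts produced.
#' @export
run_stage <- function(stage = c("generate-phantom", "fit", "infer", "compare",
                                "cluster", "show-curves", "show-data-distribution"),
                      config, overrides = list()) {
  stage <- match.arg(stage)
  config <- apply_overrides(load_config(config), overrides)
  out <- config$paths$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "config_effective.yaml"))
  log_line(out, sprintf("stage=%s seed=%s", stage, config$seed))
  set.seed(config$seed)
  res <- switch(stage,
    "generate-phantom" = stage_phantom(config),
    "fit" = stage_fit(config),
    "infer" = stage_infer(config),
    "compare" = stage_compare(config),
    "cluster" = stage_cluster(config),
    "show-curves" = stage_show_curves(config),
    "show-data-distribution" = stage_show_dist(config))
  log_line(out, sprintf("stage=%s done", stage))
  invisible(res)
}

log_line <- function(out, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = file.path(out, "run_log.txt"), append = TRUE)
}

manifest_path <- function(out, stage) file.path(out, sprintf("manifest_%s.json", stage))

write_manifest <- function(out, stage, artifacts) {
  jsonlite::write_json(c(list(stage = stage), artifacts),
                       manifest_path(out, stage), auto_unbox = TRUE, digits = NA)
}

require_stage <- function(out, stage) {
  if (!file.exists(manifest_path(out, stage))) {
    abort(sprintf("missing artifacts of stage '%s'; run it first", stage))
  }
  jsonlite::read_json(manifest_path(out, stage), simplifyVector = TRUE)
}

stage_phantom <- function(config) {
  out <- config$paths$output
  ph <- config$phantom
  spec <- phantom_spec(L = ph$L, shape = unlist(ph$shape), sigma = ph$sigma,
                       seed = ph$seed)
  res <- generate_phantom(spec, dir = file.path(out, "phantom"))
  write_manifest(out, "generate-phantom",
                 list(dir = file.path(out, "phantom"),
                      images = res$files$images,
                      covariates = res$files$covariates))
  res$files
}

resolve_images <- function(images) {
  if (length(images) == 1 && dir.exists(images)) {
    return(sort(list.files(images, pattern = "\\.(nii|nii\\.gz|mgh|mgz|thickness|area|curv)$",
                           full.names = TRUE)))
  }
  if (length(images) == 1 && grepl("[*?]", images)) return(sort(Sys.glob(images)))
  images
}

load_inputs <- function(config) {
  paths <- config$paths
  if (is.null(paths$covariates) || is.null(paths$images)) {
    abort("config must set paths$covariates and paths$images")
  }
  covariates <- read_covariates(paths$covariates)
  obs <- load_observations(resolve_images(paths$images), mask = paths$mask,
                           sigma_min = config$sigma_min)
  check_subjects(obs, covariates)
  if (config$preprocessing != "none") {
    covariates <- preprocess_covariates(covariates, config$preprocessing)
  }
  design <- if (!is.null(config$contrast)) {
    C <- do.call(rbind, lapply(config$contrast, unlist))
    split_design(covariates, build_contrast(C))
  } else {
    split_by_role(covariates, config$predictors)
  }
  list(covariates = covariates, obs = obs, design = design)
}

stage_fit <- function(config) {
  out <- config$paths$output
  inp <- load_inputs(config)
  Y <- masked_data(inp$obs)
  fit_dir <- file.path(out, "fit")
  dir.create(fit_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- list()
  for (nm in names(config$models)) {
    m <- config$models[[nm]]
    fits[[nm]] <- fit_two_stage(Y, inp$design,
                                parse_fitter_spec(m$corrector),
                                parse_fitter_spec(m$predictor),
                                chunk_size = config$chunk_size)
    # GLM predictor parameters as images, one per coefficient
    if (inherits(fits[[nm]]$predictor, "nm_glm")) {
      cf <- fits[[nm]]$predictor$coef
      for (j in seq_len(nrow(cf))) {
        write_map(cf[j, ], inp$obs,
                  file.path(fit_dir, sprintf("%s_beta%d.%s", nm, j,
                                             inp$obs$geometry$format)))
      }
    }
  }
  saveRDS(list(fits = fits, obs = inp$obs, covariates = inp$covariates,
               design = inp$design),
          file.path(fit_dir, "model_store.rds"))
  sidecar <- lapply(names(fits), function(nm) list(
    model = nm,
    corrector = config$models[[nm]]$corrector,
    predictor = config$models[[nm]]$predictor,
    df_correctors = fits[[nm]]$df_correctors,
    df_predictors_median = stats::median(fits[[nm]]$df_predictors),
    L = fits[[nm]]$L, N = fits[[nm]]$N))
  jsonlite::write_json(sidecar, file.path(fit_dir, "model_store.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out, "fit", list(store = file.path(fit_dir, "model_store.rds"),
                                  models = names(fits)))
  list(store = file.path(fit_dir, "model_store.rds"), fits = fits)
}

read_store <- function(config) {
  man <- require_stage(config$paths$output, "fit")
  readRDS(man$store)
}

stage_infer <- function(config) {
  out <- config$paths$output
  store <- read_store(config)
  map_dir <- file.path(out, "maps")
  dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- store$obs$geometry$format
  maps <- list(); files <- character(0)
  for (nm in names(store$fits)) {
    for (metric in config$inference$metrics) {
      map <- make_stat_map(store$fits[[nm]], metric,
                           gamma = config$inference$gamma,
                           T = config$inference$curve_grid, obs = store$obs)
      key <- paste0(nm, "_", metric)
      maps[[key]] <- map
      f <- file.path(map_dir, paste0(key, ".", ext))
      write_map(map, store$obs, f)
      files <- c(files, f)
      if (metric == "ftest") {
        for (wh in c("p_value", "significance")) {
          f2 <- file.path(map_dir, paste0(key, "_", wh, ".", ext))
          write_map(map, store$obs, f2, what = wh)
          files <- c(files, f2)
        }
      }
    }
  }
  saveRDS(maps, file.path(map_dir, "stat_maps.rds"))
  write_manifest(out, "infer", list(maps = files,
                                    store = file.path(map_dir, "stat_maps.rds")))
  list(maps = maps, files = files)
}

stage_compare <- function(config) {
  out <- config$paths$output
  require_stage(out, "infer")
  maps <- readRDS(file.path(out, "maps", "stat_maps.rds"))
  store <- read_store(config)
  cc <- config$compare
  models <- cc$models %||% vapply(strsplit(grep(paste0("_", cc$metric, "$"),
                                                names(maps), value = TRUE),
                                           paste0("_", cc$metric)),
                                  `[[`, character(1), 1)
  keys <- paste0(models, "_", cc$metric)
  missing <- setdiff(keys, names(maps))
  if (length(missing)) abort(sprintf("no inferred map(s): %s; run 'infer' with that metric",
                                     paste(missing, collapse = ", ")))
  cmp <- combine_maps(maps[keys], kind = cc$kind)
  ext <- store$obs$geometry$format
  f <- file.path(out, "maps", paste0("compare_", cc$kind, "_", cc$metric, ".", ext))
  write_map(cmp, store$obs, f)
  saveRDS(cmp, file.path(out, "maps", paste0("compare_", cc$kind, ".rds")))
  write_manifest(out, "compare", list(file = f, kind = cc$kind, models = models))
  list(comparison = cmp, file = f)
}

stage_cluster <- function(config) {
  out <- config$paths$output
  require_stage(out, "infer")
  store <- read_store(config)
  maps <- readRDS(file.path(out, "maps", "stat_maps.rds"))
  cl <- config$clustering
  model <- cl$model %||% names(store$fits)[1]
  key <- paste0(model, "_", cl$metric)
  if (!key %in% names(maps)) {
    abort(sprintf("no inferred map '%s'; run 'infer' with metric '%s' first",
                  key, cl$metric))
  }
  thr <- threshold_map(maps[[key]], p_threshold = cl$threshold,
                       extent = cl$cluster_extent)
  if (sum(thr$keep) < cl$n_clusters) {
    abort(sprintf("only %d observations survive the threshold; cannot form %d clusters",
                  sum(thr$keep), cl$n_clusters))
  }
  curves <- eval_curves(store$fits[[model]], T = config$inference$curve_grid)
  sub <- new_curve_set(curves$grid, curves$curves[thr$keep, , drop = FALSE],
                       ids = which(thr$keep))
  res <- cluster_curves(sub, n_clusters = cl$n_clusters,
                        weights = unlist(cl$weights),
                        standardize = isTRUE(cl$standardize))
  ext <- store$obs$geometry$format
  lab_full <- numeric(store$fits[[model]]$N)
  lab_full[thr$keep] <- res$labels
  f_lab <- file.path(out, "maps", paste0("cluster_labels_", model, ".", ext))
  write_map(lab_full, store$obs, f_lab)
  cent <- as.data.frame(t(res$centroids))
  names(cent) <- paste0("cluster_", seq_len(nrow(res$centroids)))
  cent <- cbind(grid = sub$grid, cent)
  f_cent <- file.path(out, "cluster_centroids.csv")
  write.csv(cent, f_cent, row.names = FALSE)
  jsonlite::write_json(
    list(model = model, n_clusters = cl$n_clusters,
         n_curves = sum(thr$keep),
         silhouette_mean = res$silhouette_mean,
         within_var = res$within_var, between_var = res$between_var),
    file.path(out, "cluster_diagnostics.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out, "cluster", list(labels = f_lab, centroids = f_cent))
  list(result = res, labels_file = f_lab, centroids_file = f_cent)
}

stage_show_curves <- function(config) {
  out <- config$paths$output
  store <- read_store(config)
  sc <- config$show_curves
  if (is.null(sc$coordinate)) abort("config must set show_curves$coordinate")
  fits <- store$fits[sc$models %||% names(store$fits)]
  prefix <- file.path(out, paste0("curves_",
                                  paste(unlist(sc$coordinate), collapse = "_")))
  res <- show_curves(fits, store$obs, unlist(sc$coordinate), out = prefix)
  write_manifest(out, "show-curves",
                 list(curves = paste0(prefix, "_curves.csv")))
  invisible(res)
}

stage_show_dist <- function(config) {
  out <- config$paths$output
  store <- read_store(config)
  prefix <- file.path(out, "data_distribution")
  res <- show_data_distribution(store$obs, store$covariates, prefix)
  write_manifest(out, "show-data-distribution",
                 list(pdf = paste0(prefix, ".pdf"),
                      summary = paste0(prefix, "_summary.csv")))
  invisible(res)
}
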