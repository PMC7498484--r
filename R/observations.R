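#' Load a stack of subject images as an observation matrix
#'
#' Reads one image per subject (all sharing geometry and format) and stacks
#' them into an L subjects x N observations matrix, N being the voxel or
#' vertex count. A mask restricts the analysis: either an explicit mask
#' image/logical vector, or — by default — the variance rule, which keeps
#' locations whose across-subject variance exceeds `sigma_min` (the strict
#' default 0 drops exactly-constant background).
#'
#' File order is the subject order and must match the covariate table rows;
#' use [check_subjects()] to cross-check counts and optional subject ids.
#'
#' @param paths Ordered character vector of image paths.
#' @param mask A mask image path, a logical vector of length N, or `NULL`
#'   for the variance rule.
#' @param sigma_min Variance threshold for the default mask.
#' @return An object of class `nm_obs`: `data` (L x N, full grid), `mask`
#'   (logical N), `geometry`, `paths`. Use [masked_data()] for the L x
#'   sum(mask) analysis matrix.
#' @export
load_observations <- function(paths, mask = NULL, sigma_min = 0) {
  stopifnot(length(paths) >= 2)
  first <- read_image(paths[1])
  N <- prod(first$dim)
  data <- matrix(NA_real_, length(paths), N)
  data[1, ] <- as.vector(first$data)
  for (i in seq_along(paths)[-1]) {
    im <- read_image(paths[i])
    if (im$format != first$format) {
      abort(sprintf("format mismatch: %s is %s but %s is %s",
                    basename(paths[i]), im$format, basename(paths[1]), first$format))
    }
    if (!identical(dim(im$data) %||% length(im$data),
                   dim(first$data) %||% length(first$data))) {
      abort(sprintf("geometry mismatch: %s does not match %s",
                    basename(paths[i]), basename(paths[1])))
    }
    if (first$type == "volume" &&
        max(abs(im$affine - first$affine)) > 1e-4) {
      abort(sprintf("affine mismatch: %s does not match %s",
                    basename(paths[i]), basename(paths[1])))
    }
    data[i, ] <- as.vector(im$data)
  }
  mask_vec <- resolve_mask(mask, data, N, sigma_min)
  geometry <- list(type = first$type, dim = first$dim, affine = first$affine,
                   format = first$format, template = first$template, n = N)
  structure(list(data = data, mask = mask_vec, geometry = geometry,
                 paths = paths),
            class = "nm_obs")
}

resolve_mask <- function(mask, data, N, sigma_min) {
  if (is.null(mask)) {
    v <- apply(data, 2, var)
    return(v > sigma_min)
  }
  if (is.character(mask)) {
    m <- read_image(mask)
    mv <- as.vector(m$data) != 0
  } else {
    mv <- as.logical(mask)
  }
  if (length(mv) != N) abort("mask length does not match image size")
  mv
}

#' @rdname load_observations
#' @param obs An `nm_obs`.
#' @export
masked_data <- function(obs) {
  stopifnot(inherits(obs, "nm_obs"))
  obs$data[, obs$mask, drop = FALSE]
}

#' @export
print.nm_obs <- function(x, ...) {
  cat(sprintf("<nm_obs> %d subjects x %d locations (%s %s), %d in mask\n",
              nrow(x$data), ncol(x$data), x$geometry$format, x$geometry$type,
              sum(x$mask)))
  invisible(x)
}

#' Check subject alignment between images and covariates
#'
#' Images are matched to covariate rows by order; a mismatch in count is
#' fatal. When the covariate table carries subject ids (see
#' [read_covariates()]) and `ids` are supplied (e.g. derived from file
#' names), they are cross-checked too.
#'
#' @param obs An `nm_obs`.
#' @param covariates Covariate table.
#' @param ids Optional character vector of per-image subject ids.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_subjects <- function(obs, covariates, ids = NULL) {
  L <- nrow(obs$data)
  if (L != nrow(covariates)) {
    abort(sprintf("%d images but %d covariate rows", L, nrow(covariates)))
  }
  tab_ids <- attr(covariates, "subject_id")
  if (!is.null(ids) && !is.null(tab_ids) && !identical(as.character(ids), tab_ids)) {
    abort("subject ids of images and covariate rows disagree")
  }
  invisible(TRUE)
}

#' Write a statistical or comparison map back to image space
#'
#' Places per-observation values into the mask locations of the source
#' geometry (masked-out locations are written as 0) and writes the result
#' in the input image format, preserving the affine/geometry exactly. RGB
#' comparison maps become a 4D image with 3 volumes; integer-valued maps
#' (best-model indices, cluster labels) are stored as 32-bit integers.
#'
#' @param map An `nm_stat_map`, `nm_comparison`, or numeric vector (length
#'   `sum(mask)` or full grid length).
#' @param obs The `nm_obs` the map was computed from (or any object with
#'   `mask` and `geometry`).
#' @param path Output path; extension must match the input format.
#' @param what For stat maps: `"values"`, `"p_value"` or `"significance"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, obs, path, what = "values") {
  geom <- obs$geometry %||% abort("obs must carry a geometry")
  mask <- obs$mask
  vals <- if (inherits(map, "nm_stat_map")) {
    map[[what]] %||% abort(sprintf("map has no '%s' component", what))
  } else if (inherits(map, "nm_comparison")) map$values else map

  integerish <- function(v) all(is.finite(v)) && all(v == round(v))
  place <- function(v) {
    full <- numeric(geom$n)
    if (length(v) == geom$n) full <- v
    else if (length(v) == sum(mask)) full[mask] <- v
    else abort("map length matches neither the mask nor the full grid")
    full[!is.finite(full)] <- 0
    full
  }
  if (is.matrix(vals)) {                      # rgb: 3 volumes in a 4D image
    arr <- array(apply(vals, 2, place), dim = c(geom$dim, ncol(vals)))
    return(write_image(arr, path, geom, datatype = "float"))
  }
  full <- place(vals)
  dt <- if (integerish(vals)) "int32" else "float"
  arr <- if (geom$type == "volume") array(full, dim = geom$dim) else full
  write_image(arr, path, geom, datatype = dt)
}

#' Export fitted curves and corrected data at one location
#'
#' The command-line counterpart of interactive curve inspection: given a
#' world coordinate in mm (volumes; mapped through the inverse affine to
#' the nearest voxel) or a vertex index (surfaces), exports the fitted
#' predictor curve of each model together with the corrected observations
#' (observations minus the fitted corrector component) at that location.
#'
#' @param fits A named list of `nm_fit` objects (or a single fit), all
#'   fitted on the masked observations of `obs`.
#' @param obs The `nm_obs` stack.
#' @param coordinate Length-3 mm coordinate (volume) or single 1-based
#'   vertex index (surface).
#' @param out Optional output path prefix; writes `<out>_curves.csv` and
#'   `<out>_observations.csv`.
#' @param T Curve grid size.
#' @return A list of tibbles `curves` and `observations` (invisibly if
#'   `out` is given); errors with the nearest in-mask location if the
#'   coordinate falls outside the mask.
#' @export
show_curves <- function(fits, obs, coordinate, out = NULL, T = 100) {
  if (inherits(fits, "nm_fit")) fits <- list(model = fits)
  stopifnot(inherits(obs, "nm_obs"))
  loc <- locate_observation(obs, coordinate)
  midx <- cumsum(obs$mask)[loc]       # index within the masked matrix
  curves <- purrr::map_dfr(names(fits), function(nm) {
    cs <- eval_curves(fits[[nm]], T = T)
    tibble(model = nm, grid = cs$grid, value = cs$curves[midx, ])
  })
  observations <- purrr::map_dfr(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble(model = nm, predictor = f$XP[, 1],
           corrected = f$Y[, midx] - f$fitted_corrector[, midx])
  })
  out_list <- list(curves = curves, observations = observations,
                   location = loc)
  if (!is.null(out)) {
    write.csv(curves, paste0(out, "_curves.csv"), row.names = FALSE)
    write.csv(observations, paste0(out, "_observations.csv"), row.names = FALSE)
    return(invisible(out_list))
  }
  out_list
}

# Map a user coordinate to a linear in-mask grid index.
locate_observation <- function(obs, coordinate) {
  geom <- obs$geometry
  if (geom$type == "surface") {
    v <- as.integer(coordinate[1])
    if (is.na(v) || v < 1 || v > geom$n) {
      abort(sprintf("vertex index %s outside [1, %d]", coordinate[1], geom$n))
    }
    if (!obs$mask[v]) abort(sprintf("vertex %d is outside the analysis mask", v))
    return(v)
  }
  stopifnot(length(coordinate) == 3)
  vox <- round(solve(geom$affine) %*% c(coordinate, 1))[1:3] + 1
  if (any(vox < 1) || any(vox > geom$dim)) {
    abort(sprintf("mm coordinate (%s) maps outside the volume",
                  paste(coordinate, collapse = ", ")))
  }
  lin <- vox[1] + (vox[2] - 1) * geom$dim[1] + (vox[3] - 1) * prod(geom$dim[1:2])
  if (!obs$mask[lin]) {
    masked <- which(obs$mask)
    co <- arrayInd(masked, geom$dim)
    mm <- t(geom$affine %*% rbind(t(co - 1), 1))[, 1:3, drop = FALSE]
    nearest <- mm[which.min(rowSums(sweep(mm, 2, coordinate)^2)), ]
    abort(sprintf(
      "coordinate (%s) is outside the analysis mask; nearest in-mask location is (%s)",
      paste(coordinate, collapse = ", "),
      paste(round(nearest, 2), collapse = ", ")))
  }
  lin
}

#' Export data-distribution summaries
#'
#' Static counterparts of interactive data exploration: univariate density
#' plots of every covariate, pairwise covariate scatter plots, and a
#' density of the per-subject mean observation inside the mask, written as
#' a single multi-page PDF plus a CSV of summary statistics.
#'
#' @param obs An `nm_obs`.
#' @param covariates Covariate table.
#' @param out Output path prefix; writes `<out>.pdf` and `<out>_summary.csv`.
#' @return Tibble of per-covariate summary statistics (invisibly).
#' @export
show_data_distribution <- function(obs, covariates, out) {
  covariates <- as_covariate_table(covariates)
  Y <- masked_data(obs)
  long <- tidyr::pivot_longer(covariates, dplyr::everything(),
                              names_to = "covariate")
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~covariate, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::ggtitle("Covariate distributions")
  subj <- tibble(mean_observation = rowMeans(Y))
  p2 <- ggplot2::ggplot(subj, ggplot2::aes(.data$mean_observation)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::theme_minimal() +
    ggplot2::ggtitle("Per-subject mean observation (in mask)")
  grDevices::pdf(paste0(out, ".pdf"), width = 8, height = 6)
  print(p1)
  if (ncol(covariates) >= 2) {
    pairs_df <- tidyr::expand_grid(a = names(covariates), b = names(covariates))
    pairs_df <- dplyr::filter(pairs_df, .data$a < .data$b)
    for (i in seq_len(nrow(pairs_df))) {
      d <- tibble(x = covariates[[pairs_df$a[i]]], y = covariates[[pairs_df$b[i]]])
      print(ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
              ggplot2::geom_point(alpha = 0.6) +
              ggplot2::labs(x = pairs_df$a[i], y = pairs_df$b[i]) +
              ggplot2::theme_minimal())
    }
  }
  print(p2)
  grDevices::dev.off()
  summary_tab <- dplyr::summarise(
    dplyr::group_by(long, .data$covariate),
    mean = mean(.data$value), sd = sd(.data$value),
    min = min(.data$value), max = max(.data$value))
  write.csv(summary_tab, paste0(out, "_summary.csv"), row.names = FALSE)
  invisible(summary_tab)
}
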