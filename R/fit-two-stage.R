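#' Two-stage corrector/predictor fitting
#'
#' The workhorse of the analysis. Confounder effects are removed first by
#' fitting the corrector model `Y = f_C(X_C) + E_C` to the observations;
#' the predictor model `E_C = f_P(X_P) + E` is then fitted to the corrector
#' residuals. Because the stages are fitted separately, any family may be
#' used at either stage. A constant (intercept) column is always part of the
#' corrector stage — with no correctors at all the corrector model reduces
#' to the observation means, so the predictor sees mean-centered data — and
#' the intercept is never counted in the reported degrees of freedom.
#'
#' @param Y L x N observation matrix (subjects by voxels/vertices), already
#'   restricted to the analysis mask.
#' @param design An `nm_design` from [split_design()]/[split_by_role()], or
#'   a bare `list(XC = , XP = )` of matrices (`XC` may have zero columns).
#' @param corrector_spec,predictor_spec Fitter specs ([spec_glm()],
#'   [spec_gam()], [spec_svr()]).
#' @param chunk_size Observations are processed in contiguous chunks of this
#'   size; results are independent of the choice.
#' @return An object of class `nm_fit` holding both stage fits, fitted
#'   matrices, residuals, per-stage degrees of freedom and the training
#'   predictor range.
#' @export
fit_two_stage <- function(Y, design, corrector_spec = spec_glm(1),
                          predictor_spec = spec_glm(1), chunk_size = Inf) {
  Y <- as_obs_matrix(Y)
  XC <- as_design_matrix(design$XC, nrow(Y))
  XP <- as_design_matrix(design$XP, nrow(Y))
  if (ncol(XP) < 1) abort("predictor design has no columns")

  corrector <- fit_stage(corrector_spec, XC, Y, intercept = TRUE,
                         chunk_size = chunk_size)
  resid_C <- Y - corrector$fitted
  # the predictor stage carries its own intercept so that an uncentered
  # predictor is implicitly centered; the corrector residuals already have
  # zero mean, so that intercept estimates ~0 and is never counted as a
  # degree of freedom
  predictor <- fit_stage(predictor_spec, XP, resid_C, intercept = TRUE,
                         chunk_size = chunk_size)
  fitted_full <- corrector$fitted + predictor$fitted

  structure(list(
    corrector = corrector, predictor = predictor,
    corrector_spec = corrector_spec, predictor_spec = predictor_spec,
    Y = Y, fitted_corrector = corrector$fitted, fitted = fitted_full,
    residuals = Y - fitted_full,
    df_correctors = stage_df(corrector),
    df_predictors = pmax(stage_df(predictor), 1),
    predictor_range = apply(XP, 2, range),
    predictor_means = colMeans(XP),
    XP = XP, XC = XC,
    design = if (inherits(design, "nm_design")) design else NULL,
    L = nrow(Y), N = ncol(Y)
  ), class = "nm_fit")
}

# Dispatch a fitter spec onto one stage design.
fit_stage <- function(spec, X, Y, intercept, chunk_size = Inf) {
  stopifnot(inherits(spec, "nm_fitter_spec"))
  if (ncol(X) == 0) {
    if (!intercept) abort("empty design without intercept")
    return(fit_glm(X, Y, intercept = TRUE, chunk_size = chunk_size))
  }
  switch(spec$family,
    glm = fit_glm(X, Y, degrees = spec$degrees, intercept = intercept,
                  chunk_size = chunk_size),
    gam = fit_gam(X, Y, smoothers = spec$smoothers, max_iter = spec$max_iter,
                  tol = spec$tol, intercept = intercept,
                  chunk_size = chunk_size),
    svr = fit_svr(X, Y, kernel = spec$kernel, eps = spec$eps,
                  cost = spec$cost, gamma = spec$gamma, degree = spec$degree,
                  coef0 = spec$coef0, chunk_size = chunk_size),
    abort(sprintf("unknown fitter family '%s'", spec$family))
  )
}

#' Predict from a two-stage fit
#'
#' Evaluates corrector plus predictor components at new covariate values.
#' When the model was built from an `nm_design`, `newdata` is a covariate
#' table with the original columns and is pushed through the stored
#' contrast; otherwise pass a `list(XC = , XP = )`. Predictor values outside
#' the training range are allowed but flagged with a warning and an
#' `"extrapolated"` attribute.
#'
#' @param object An `nm_fit`.
#' @param newdata Covariate table or `list(XC, XP)`.
#' @param ... Unused.
#' @return L' x N matrix of predictions with attribute `"extrapolated"`.
#' @export
predict.nm_fit <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(c("XC", "XP") %in% names(newdata))) {
    XC <- as_design_matrix(newdata$XC, NULL)
    XP <- as_design_matrix(newdata$XP, NULL)
  } else {
    if (is.null(object$design)) {
      abort("model was fitted from bare matrices; supply newdata as list(XC, XP)")
    }
    X <- covariate_matrix(newdata)
    ct <- object$design$contrast
    XP <- X %*% ct$C
    XC <- (X %*% ct$C0)[, object$design$kept_correctors, drop = FALSE]
  }
  extrap <- any(sweep(XP, 2, object$predictor_range[1, ], `<`) |
                sweep(XP, 2, object$predictor_range[2, ], `>`))
  if (extrap) warn("prediction extrapolates beyond the training predictor range")
  out <- predict(object$corrector, XC) + predict(object$predictor, XP)
  attr(out, "extrapolated") <- extrap
  out
}

#' Evaluate fitted predictor curves on a common grid
#'
#' Evaluates the predictor component only — correctors are held at their
#' reference (the corrector stage absorbs them together with the intercept,
#' so the curve lives on the corrected-observation scale) — on a uniform
#' grid of `T` points spanning the training range of one predictor column.
#' With several predictor columns the remaining ones are held at their
#' training means.
#'
#' @param model An `nm_fit`.
#' @param T Number of grid points (`>= 5`).
#' @param predictor Index of the predictor column to sweep.
#' @return An object of class `nm_curves`: `grid` (length `T`), `curves`
#'   (N x T matrix, one row per observation) and `ids`.
#' @export
eval_curves <- function(model, T = 100, predictor = 1L) {
  stopifnot(inherits(model, "nm_fit"), T >= 5)
  rng <- model$predictor_range[, predictor]
  grid <- seq(rng[1], rng[2], length.out = T)
  XP <- matrix(rep(model$predictor_means, each = T), nrow = T)
  XP[, predictor] <- grid
  vals <- predict(model$predictor, XP)          # T x N
  new_curve_set(grid, t(vals), ids = seq_len(model$N))
}

#' Construct a curve set
#'
#' Bundles curves evaluated on a shared, strictly increasing grid (at least
#' 5 points) into the container used by clustering and plotting. Useful for
#' subsetting the output of [eval_curves()] to significant observations.
#'
#' @param grid Strictly increasing numeric grid of length `T >= 5`.
#' @param curves N x T matrix, one curve per row.
#' @param ids Observation identifiers (defaults to row numbers).
#' @return An object of class `nm_curves`.
#' @export
new_curve_set <- function(grid, curves, ids = seq_len(nrow(curves))) {
  stopifnot(all(diff(grid) > 0), length(grid) >= 5,
            ncol(curves) == length(grid))
  structure(list(grid = grid, curves = curves, ids = ids),
            class = "nm_curves")
}

#' @export
print.nm_fit <- function(x, ...) {
  cat(sprintf(
    "<nm_fit> L=%d subjects, N=%d observations\n  corrector: %s (df=%g)\n  predictor: %s (df=%s)\n",
    x$L, x$N, x$corrector_spec$family %||% "mean", x$df_correctors,
    x$predictor_spec$family,
    if (length(unique(x$df_predictors)) == 1) format(x$df_predictors[1])
    else sprintf("per-observation, median %g", stats::median(x$df_predictors))))
  invisible(x)
}

#' @export
print.nm_curves <- function(x, ...) {
  cat(sprintf("<nm_curves> %d curves on a %d-point grid [%g, %g]\n",
              nrow(x$curves), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
tidy.nm_fit <- function(x, ...) {
  if (inherits(x$predictor, "nm_glm")) {
    cf <- x$predictor$coef
    tibble(
      observation = rep(seq_len(ncol(cf)), each = nrow(cf)),
      term = rep(rownames(cf) %||% paste0("b", seq_len(nrow(cf))), ncol(cf)),
      estimate = as.vector(cf)
    )
  } else {
    tibble(
      observation = seq_len(x$N),
      term = "df_predictor",
      estimate = rep_len(x$df_predictors, x$N)
    )
  }
}

#' @export
glance.nm_fit <- function(x, ...) {
  ssf <- colSums(x$residuals^2)
  tibble(
    n_obs = x$N, L = x$L,
    df_correctors = x$df_correctors,
    df_predictors = mean(x$df_predictors),
    mean_mse = mean(ssf / x$L)
  )
}

#' @export
tidy.nm_curves <- function(x, ...) {
  tibble(
    id = rep(x$ids, each = length(x$grid)),
    grid = rep(x$grid, nrow(x$curves)),
    value = as.vector(t(x$curves))
  )
}

#' @export
autoplot.nm_curves <- function(object, max_curves = 200, ...) {
  d <- tidy(object)
  keep <- unique(d$id)
  if (length(keep) > max_curves) {
    keep <- keep[round(seq(1, length(keep), length.out = max_curves))]
    d <- dplyr::filter(d, .data$id %in% keep)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$grid, .data$value, group = .data$id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "predictor", y = "fitted effect") +
    ggplot2::theme_minimal()
}
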