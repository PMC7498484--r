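#' Goodness-of-fit and complexity metrics
#'
#' Scalar building blocks for the statistical maps. Conventions:
#'
#' * `mse()` is the squared residual norm `||y - f(X)||^2` (a sum over
#'   subjects, not a mean). Where a per-sample mean squared error is
#'   semantically required — the Gaussian log-likelihood inside [aic()] —
#'   divide by `L`; both scales are documented at their use sites.
#' * `r2()` is `1 - SS_res / SS_y` with `SS_y` the total sum of squares
#'   about the observation mean; a zero-variance observation yields `NA`.
#' * `aic()` is `2k - 2 LLR` with
#'   `LLR = -(L/2) (log(2 pi MSE) + 1)` and `MSE` the per-sample mean;
#'   a zero MSE yields `-Inf` with a warning.
#'
#' @param y,yhat Numeric vectors of equal length (`L >= 2`), or matrices
#'   with subjects in rows (metrics are then computed per column).
#' @return Numeric scalar (or vector for matrix input).
#' @export
mse <- function(y, yhat) {
  check_pair(y, yhat)
  if (is.matrix(y)) colSums((y - yhat)^2) else sum((y - yhat)^2)
}

#' @rdname mse
#' @export
r2 <- function(y, yhat) {
  check_pair(y, yhat)
  if (!is.matrix(y)) { y <- cbind(y); yhat <- cbind(yhat) }
  ss_res <- colSums((y - yhat)^2)
  ss_y <- colSums(sweep(y, 2, colMeans(y))^2)
  out <- 1 - ss_res / ss_y
  out[ss_y == 0] <- NA_real_
  if (length(out) == 1) out <- unname(out)
  out
}

check_pair <- function(y, yhat) {
  if (NROW(y) != NROW(yhat) || NCOL(y) != NCOL(yhat)) {
    abort("y and yhat must have matching dimensions")
  }
  if (NROW(y) < 2) abort("need at least 2 subjects")
}

#' @rdname mse
#' @param mse_value Per-sample mean squared error (`> 0`).
#' @param k Total parameter count of the model.
#' @param L Sample size.
#' @export
aic <- function(mse_value, k, L) {
  out <- 2 * k + L * (log(2 * pi * mse_value) + 1)
  if (any(mse_value == 0)) {
    warn("AIC is -Inf for a perfect fit (MSE = 0)")
    out[mse_value == 0] <- -Inf
  }
  out
}

#' Nested-model F-test
#'
#' Tests whether the full model (correctors and predictors) explains
#' significantly more variance than the restricted model (correctors only):
#' `f = ((SS_res - SS_full) / SS_full) * ((L - df_full) / (df_full - df_restricted))`,
#' with `SS_res` the restricted and `SS_full` the full residual sum of
#' squares. The p-value is the upper-tail probability of the F distribution
#' with `(df_full - df_restricted, L - df_full)` degrees of freedom.
#' Negative statistics (possible when a non-least-squares predictor stage
#' increases the residual) are clamped to zero.
#'
#' @param ss_res,ss_full Restricted and full residual sums of squares
#'   (vectorized).
#' @param df_full,df_restricted Model degrees of freedom,
#'   `df_full > df_restricted`, `L > df_full`.
#' @param L Sample size.
#' @return A list with numeric vectors `f_score` and `p_value`.
#' @export
f_test <- function(ss_res, ss_full, df_full, df_restricted, L) {
  f_nested(ss_res, ss_full, df_full, df_restricted, L)
}

f_nested <- function(ss_res, ss_full, df_full, df_restricted, L) {
  if (any(df_full <= df_restricted)) abort("df_full must exceed df_restricted")
  if (any(L <= df_full)) abort("sample size must exceed df_full")
  zero_full <- ss_full <= 0
  if (any(zero_full)) warn("SS_full = 0: p-value set to 0")
  ssf <- pmax(ss_full, .Machine$double.xmin)
  f <- ((ss_res - ssf) / ssf) * ((L - df_full) / (df_full - df_restricted))
  f <- pmax(f, 0)
  p <- pf(f, df_full - df_restricted, L - df_full, lower.tail = FALSE)
  f[zero_full] <- Inf
  p[zero_full] <- 0
  list(f_score = f, p_value = p)
}

#' Curve-shape complexity and penalized residual metrics
#'
#' `curve_abruptness()` measures the roughness of a fitted curve as the
#' integral over the predictor grid of its squared second derivative,
#' estimated by central second finite differences on the uniform grid and
#' integrated by the trapezoidal rule over the interior points (an
#' absolute-value variant is available). A straight line has abruptness 0,
#' so a complex fitter that happens to produce a linear curve is penalized
#' exactly like the linear model — the shape, not the parameter count, pays
#' the penalty.
#'
#' `prss()` adds the scaled roughness to the residual error:
#' `PRSS = MSE + gamma * c_abruptness` (with `MSE` on the squared-norm
#' scale, see [mse()]). `vnprss()` normalizes PRSS by the curve's energy
#' about the observation mean, `c_variance = ||f(X) - ybar||^2` over the
#' grid, an adaptation for high-variability data; a constant curve has zero
#' energy and yields `NA`.
#'
#' @param curve Numeric vector: the fitted curve on the grid (`T >= 5`).
#' @param grid Strictly increasing, uniform predictor grid.
#' @param roughness `"squared"` (default) or `"abs"` integrand.
#' @return Numeric scalar.
#' @export
curve_abruptness <- function(curve, grid, roughness = c("squared", "abs")) {
  roughness <- match.arg(roughness)
  T <- length(grid)
  stopifnot(T >= 5, length(curve) == T, all(diff(grid) > 0))
  h <- grid[2] - grid[1]
  i <- 2:(T - 1)
  d2 <- (curve[i - 1] - 2 * curve[i] + curve[i + 1]) / h^2
  g <- if (roughness == "squared") d2^2 else abs(d2)
  # trapezoid over the interior grid
  sum((g[-1] + g[-length(g)]) / 2) * h
}

#' @rdname curve_abruptness
#' @param mse_value Residual error on the squared-norm scale.
#' @param gamma Nonnegative penalty weight.
#' @export
prss <- function(curve, grid, mse_value, gamma = 1,
                 roughness = c("squared", "abs")) {
  stopifnot(gamma >= 0)
  mse_value + gamma * curve_abruptness(curve, grid, roughness)
}

#' @rdname curve_abruptness
#' @param prss_value A value from [prss()].
#' @param ybar Observation mean (reference level for the curve energy).
#' @export
vnprss <- function(prss_value, curve, grid, ybar) {
  stopifnot(length(curve) == length(grid))
  c_var <- sum((curve - ybar)^2)
  if (c_var == 0) return(NA_real_)
  prss_value / c_var
}

#' Build a statistical map from a two-stage fit
#'
#' Vectorizes the goodness-of-fit metrics over all fitted observations.
#' For `"ftest"` the map carries the F statistic as its value plus
#' `p_value` and `significance` (`1 - p`) arrays; `"prss"`/`"vnprss"`
#' evaluate the predictor curves on a `T`-point grid first. The AIC
#' parameter count is taken as `df_correctors + df_predictors`, the same
#' bookkeeping the F-test uses.
#'
#' @param fit An `nm_fit` from [fit_two_stage()].
#' @param metric One of `"mse"`, `"r2"`, `"aic"`, `"ftest"`, `"prss"`,
#'   `"vnprss"`.
#' @param gamma Roughness weight for PRSS/VNPRSS.
#' @param T Curve grid size for PRSS/VNPRSS.
#' @param obs Optional `nm_obs` stack; attaches geometry and mask so the
#'   map can be written back in the input image format.
#' @param roughness Passed to [curve_abruptness()].
#' @return An object of class `nm_stat_map`.
#' @export
make_stat_map <- function(fit, metric = c("mse", "r2", "aic", "ftest", "prss", "vnprss"),
                          gamma = 1, T = 100, obs = NULL,
                          roughness = "squared") {
  metric <- match.arg(metric)
  stopifnot(inherits(fit, "nm_fit"))
  ss_full <- colSums(fit$residuals^2)
  ss_res <- colSums((fit$Y - fit$fitted_corrector)^2)
  df_full <- fit$df_correctors + fit$df_predictors
  p <- NULL; signif <- NULL
  values <- switch(metric,
    mse = ss_full,
    r2 = r2(fit$Y, fit$fitted),
    aic = aic(ss_full / fit$L, df_full, fit$L),
    ftest = {
      ft <- f_nested(ss_res, ss_full, df_full, fit$df_correctors, fit$L)
      p <- ft$p_value; signif <- 1 - p
      ft$f_score
    },
    prss = ,
    vnprss = {
      cs <- eval_curves(fit, T = T)
      v <- vapply(seq_len(fit$N), function(i) {
        pv <- prss(cs$curves[i, ], cs$grid, ss_full[i], gamma, roughness)
        if (metric == "prss") pv else
          vnprss(pv, cs$curves[i, ], cs$grid, mean(fit$Y[, i]) - mean(fit$fitted_corrector[, i]))
      }, numeric(1))
      v
    })
  structure(list(
    values = unname(values), metric = metric,
    p_value = p, significance = signif,
    df = list(correctors = fit$df_correctors, predictors = fit$df_predictors),
    L = fit$L,
    geometry = obs$geometry, mask = obs$mask
  ), class = "nm_stat_map")
}

#' @export
print.nm_stat_map <- function(x, ...) {
  cat(sprintf("<nm_stat_map> metric=%s, N=%d observations, value range [%g, %g]\n",
              x$metric, length(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.nm_stat_map <- function(x, ...) {
  out <- tibble(observation = seq_along(x$values), value = x$values)
  if (!is.null(x$p_value)) out$p_value <- x$p_value
  out
}

#' @export
glance.nm_stat_map <- function(x, ...) {
  tibble(metric = x$metric, n = length(x$values),
         mean = mean(x$values[is.finite(x$values)]),
         n_p_lt_05 = if (is.null(x$p_value)) NA_integer_ else sum(x$p_value < 0.05))
}

#' Threshold a significance map with cluster-extent filtering
#'
#' Applies an uncorrected (or Bonferroni-adjusted) p-value threshold and
#' removes connected components smaller than `extent` voxels under
#' 6-connectivity (face neighbors). Surface geometries have no spatial
#' lattice here, so extent filtering applies to volumes only.
#'
#' @param map An `nm_stat_map` carrying p-values and a volume geometry
#'   (build it with `make_stat_map(..., metric = "ftest", obs = )`).
#' @param p_threshold Significance threshold on the p-values.
#' @param extent Minimum surviving cluster size in voxels (1 = none).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A list: `keep` (logical over the map's observations), `labels`
#'   (integer cluster id, 0 outside), `n_clusters`, `cluster_sizes`.
#' @export
threshold_map <- function(map, p_threshold = 0.001, extent = 1,
                          adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(map, "nm_stat_map"))
  if (is.null(map$p_value)) abort("map carries no p-values; use an F-test map")
  p <- map$p_value
  if (adjust == "bonferroni") p <- pmin(p * length(p), 1)
  sig <- p < p_threshold
  if (extent <= 1 || is.null(map$geometry) || map$geometry$type != "volume") {
    labels <- cumsum(sig) * sig
    return(list(keep = sig, labels = as.integer(labels),
                n_clusters = sum(sig), cluster_sizes = rep(1L, sum(sig))))
  }
  vol <- array(FALSE, dim = map$geometry$dim)
  vol[which(map$mask)[sig]] <- TRUE
  lab <- label_components6(vol)
  sizes <- tabulate(lab[lab > 0])
  keep_cluster <- which(sizes >= extent)
  lab[!(lab %in% keep_cluster)] <- 0L
  # relabel compactly
  relab <- match(lab, c(0L, keep_cluster)) - 1L
  lab_masked <- relab[which(map$mask)]
  keep <- lab_masked > 0
  list(keep = keep, labels = as.integer(lab_masked),
       n_clusters = length(keep_cluster),
       cluster_sizes = sizes[keep_cluster])
}

# 6-connectivity connected components on a logical 3D array (iterative BFS).
label_components6 <- function(vol) {
  d <- dim(vol)
  lab <- array(0L, d)
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nxt <- 0L
  idx_all <- which(vol)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      for (k in seq_len(6)) {
        p <- co + nbr[k, ]
        if (any(p < 1) || any(p > d)) next
        lin <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (vol[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}
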