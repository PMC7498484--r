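#' Fitter specifications
#'
#' A fitter spec names the curve-fitting family used for one stage of the
#' two-stage procedure and its per-covariate basis/smoother choices or
#' kernel hyperparameters. Three families are available:
#'
#' * `spec_glm()` — multiple linear regression, nonlinearity through a raw
#'   polynomial expansion of each column (`degrees`, recycled across
#'   columns). A degree-`d` covariate contributes `d` degrees of freedom.
#' * `spec_gam()` — additive model estimated by backfitting; one smoother
#'   per covariate (see [sm_linear()] and friends).
#' * `spec_svr()` — epsilon-insensitive support vector regression with a
#'   polynomial or radial basis function kernel; unlike the other two it
#'   models interactions between covariates.
#'
#' @param degrees Integer polynomial degree(s) `>= 1`, recycled over design
#'   columns.
#' @return An object of class `nm_fitter_spec`.
#' @export
spec_glm <- function(degrees = 1) {
  if (any(degrees < 1) || any(degrees != round(degrees))) {
    abort("polynomial degrees must be integers >= 1")
  }
  structure(list(family = "glm", degrees = as.integer(degrees)),
            class = "nm_fitter_spec")
}

#' @rdname spec_glm
#' @param smoothers A single smoother or a list of smoothers (one per design
#'   column, recycled), from [sm_linear()], [sm_poly()], [sm_bspline()],
#'   [sm_nspline()].
#' @param max_iter,tol Backfitting controls: maximum number of full sweeps
#'   and the convergence threshold on the maximum absolute change of any
#'   component between sweeps.
#' @export
spec_gam <- function(smoothers = sm_bspline(8), max_iter = 500, tol = 1e-6) {
  if (inherits(smoothers, "nm_smoother")) smoothers <- list(smoothers)
  stopifnot(all(vapply(smoothers, inherits, logical(1), "nm_smoother")))
  structure(list(family = "gam", smoothers = smoothers,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "nm_fitter_spec")
}

#' @rdname spec_glm
#' @param kernel `"rbf"` or `"polynomial"`.
#' @param eps Half-width of the insensitive tube (`>= 0`).
#' @param cost Box constraint `C > 0` balancing flatness against errors
#'   beyond the tube.
#' @param gamma RBF kernel width parameter (`k(u,v) = exp(-gamma ||u-v||^2)`).
#' @param degree,coef0 Polynomial kernel parameters
#'   (`k(u,v) = (u.v + coef0)^degree`).
#' @export
spec_svr <- function(kernel = c("rbf", "polynomial"), eps = 0.1, cost = 1,
                     gamma = 1, degree = 3, coef0 = 1) {
  kernel <- match.arg(kernel)
  if (eps < 0 || cost <= 0 || gamma <= 0 || degree < 1) {
    abort("SVR hyperparameters out of range: need eps >= 0, cost > 0, gamma > 0, degree >= 1")
  }
  structure(list(family = "svr", kernel = kernel, eps = eps, cost = cost,
                 gamma = gamma, degree = as.integer(degree), coef0 = coef0),
            class = "nm_fitter_spec")
}

#' @export
print.nm_fitter_spec <- function(x, ...) {
  detail <- switch(x$family,
    glm = sprintf("degrees = %s", paste(x$degrees, collapse = ",")),
    gam = paste(vapply(x$smoothers, function(s) s$label, character(1)), collapse = ", "),
    svr = sprintf("kernel = %s, eps = %g, cost = %g", x$kernel, x$eps, x$cost))
  cat(sprintf("<nm_fitter_spec> %s (%s)\n", x$family, detail))
  invisible(x)
}

#' Smoothers for additive-model fitting
#'
#' Per-covariate smoother descriptors for [spec_gam()]. Each carries its
#' degrees-of-freedom contribution: 1 for a linear smoother, the polynomial
#' order for a polynomial smoother, and the user-chosen basis dimension for
#' B-spline and natural-spline smoothers (knots are placed at quantiles of
#' the covariate; natural splines are linear beyond the boundary knots).
#'
#' @return An object of class `nm_smoother`.
#' @export
sm_linear <- function() {
  structure(list(kind = "linear", df = 1L, label = "linear"),
            class = "nm_smoother")
}

#' @rdname sm_linear
#' @param degree Polynomial order (`>= 1`).
#' @export
sm_poly <- function(degree) {
  stopifnot(degree >= 1)
  structure(list(kind = "poly", degree = as.integer(degree),
                 df = as.integer(degree), label = sprintf("poly(%d)", degree)),
            class = "nm_smoother")
}

#' @rdname sm_linear
#' @param df Basis dimension (`>= 3`).
#' @export
sm_bspline <- function(df) {
  stopifnot(df >= 3)
  structure(list(kind = "bspline", df = as.integer(df),
                 label = sprintf("bspline(df=%d)", df)),
            class = "nm_smoother")
}

#' @rdname sm_linear
#' @export
sm_nspline <- function(df) {
  stopifnot(df >= 3)
  structure(list(kind = "nspline", df = as.integer(df),
                 label = sprintf("nspline(df=%d)", df)),
            class = "nm_smoother")
}

# --- internal basis machinery -------------------------------------------

# Basis for one smoother on one covariate.  Returns list(train = matrix,
# eval = function(xnew) matrix) so prediction reuses the training knots.
smoother_basis <- function(x, sm) {
  switch(sm$kind,
    linear = list(train = cbind(x),
                  eval = function(z) cbind(z), df = 1L),
    poly = {
      d <- sm$degree
      list(train = outer(x, seq_len(d), `^`),
           eval = function(z) outer(z, seq_len(d), `^`), df = d)
    },
    bspline = {
      if (length(unique(x)) < sm$df + 1) {
        abort(sprintf("B-spline smoother with df=%d needs at least %d distinct values",
                      sm$df, sm$df + 1))
      }
      B <- splines::bs(x, df = sm$df)
      list(train = unclass(B)[, , drop = FALSE],
           eval = function(z) suppressWarnings(unclass(predict(B, z))),
           df = sm$df)
    },
    nspline = {
      if (length(unique(x)) < sm$df + 1) {
        abort(sprintf("natural-spline smoother with df=%d needs at least %d distinct values",
                      sm$df, sm$df + 1))
      }
      B <- splines::ns(x, df = sm$df)
      list(train = unclass(B)[, , drop = FALSE],
           eval = function(z) suppressWarnings(unclass(predict(B, z))),
           df = sm$df)
    },
    abort(sprintf("unknown smoother kind '%s'", sm$kind))
  )
}

# Raw polynomial expansion of a design matrix; one block per column.
poly_expand <- function(X, degrees) {
  degrees <- rep_len(as.integer(degrees), ncol(X))
  blocks <- lapply(seq_len(ncol(X)), function(j) {
    b <- outer(X[, j], seq_len(degrees[j]), `^`)
    colnames(b) <- paste0(colnames(X)[j] %||% paste0("x", j),
                          ifelse(seq_len(degrees[j]) == 1, "",
                                 paste0("^", seq_len(degrees[j]))))
    b
  })
  out <- do.call(cbind, blocks)
  attr(out, "degrees") <- degrees
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
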