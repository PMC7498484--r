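#' Fit a mass-univariate linear model with polynomial expansion
#'
#' Ordinary least squares of every observation column of `Y` on the same
#' design, `y = X beta + e`, minimizing the squared error norm. Nonlinear
#' covariate effects are modeled through a raw polynomial expansion of each
#' design column. All observations share one QR decomposition, so the cost
#' is one factorization plus a triangular solve per chunk; chunking the
#' observation axis is numerically exact (bit-identical to a single solve).
#'
#' @param X Numeric design matrix, L subjects x m columns (m may be 0 for an
#'   intercept-only model).
#' @param Y Numeric observation matrix, L x N (a vector is treated as one
#'   column).
#' @param degrees Polynomial degree per design column (recycled).
#' @param intercept Prepend a constant column? The intercept never counts
#'   toward the model degrees of freedom.
#' @param chunk_size Number of observation columns solved per block.
#' @return An object of class `nm_glm`: `coef` (p x N), `fitted` (L x N),
#'   `df` (sum of the per-column degrees), plus the expansion bookkeeping
#'   needed by [predict.nm_glm()].
#' @export
fit_glm <- function(X, Y, degrees = 1, intercept = TRUE, chunk_size = Inf) {
  Y <- as_obs_matrix(Y)
  X <- as_design_matrix(X, nrow(Y))
  if (ncol(X) > 0) {
    E <- poly_expand(X, degrees)
    degrees <- attr(E, "degrees")
  } else {
    E <- matrix(0, nrow(Y), 0)
    degrees <- integer(0)
  }
  D <- if (intercept) cbind(`(Intercept)` = 1, E) else E
  if (ncol(D) == 0) abort("empty design: no columns and no intercept")
  if (ncol(D) >= nrow(D)) {
    abort(sprintf("expanded design has %d columns for %d subjects; underdetermined",
                  ncol(D), nrow(D)))
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dep <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    abort(sprintf("expanded design is rank deficient; dependent column(s): %s",
                  paste(dep, collapse = ", ")))
  }
  coefs <- matrix(NA_real_, ncol(D), ncol(Y),
                  dimnames = list(colnames(D), colnames(Y)))
  fitted <- matrix(NA_real_, nrow(Y), ncol(Y))
  for (idx in chunk_indices(ncol(Y), chunk_size)) {
    b <- qr.coef(qrD, Y[, idx, drop = FALSE])
    coefs[, idx] <- b
    fitted[, idx] <- mm_bycol(D, b)
  }
  structure(list(
    coef = coefs, fitted = fitted, df = sum(degrees),
    degrees = degrees, intercept = intercept,
    n_covariates = ncol(X), L = nrow(Y)
  ), class = c("nm_glm", "nm_stage_fit"))
}

#' @export
predict.nm_glm <- function(object, newdata, ...) {
  X <- as_design_matrix(newdata, NULL)
  if (ncol(X) != object$n_covariates) {
    abort(sprintf("newdata has %d columns; model was trained on %d",
                  ncol(X), object$n_covariates))
  }
  E <- if (ncol(X) > 0) poly_expand(X, object$degrees) else matrix(0, nrow(X), 0)
  D <- if (object$intercept) cbind(1, E) else E
  D %*% object$coef
}

stage_df <- function(fit) UseMethod("stage_df")
#' @export
stage_df.nm_stage_fit <- function(fit) fit$df

as_obs_matrix <- function(Y) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) abort("observations contain missing values")
  Y
}

as_design_matrix <- function(X, L) {
  if (is.null(X)) X <- matrix(0, L, 0)
  if (is.data.frame(X)) X <- covariate_matrix(X)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(L) && nrow(X) != L) {
    abort(sprintf("design has %d rows but observations have %d", nrow(X), L))
  }
  X
}

# Column-by-column matrix product.  BLAS rounds a matrix-vector product
# differently from a multi-column product, so products inside the chunked
# fitting loops go through this helper to keep results bit-identical for
# every chunk size.
mm_bycol <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(ncol(B))) out[, i] <- A %*% B[, i]
  out
}

#' Contiguous chunk index blocks
#'
#' Splits `1:n` into contiguous blocks of at most `chunk_size`, covering the
#' range exactly once (the last block may be short). Fitting and map
#' construction iterate these blocks so that memory stays bounded while
#' results remain identical to an unchunked run.
#'
#' @param n Number of observation columns.
#' @param chunk_size Maximum block length (`>= 1`; `Inf` for one block).
#' @return A list of integer index vectors.
#' @export
chunk_indices <- function(n, chunk_size = Inf) {
  stopifnot(n >= 0, chunk_size >= 1)
  if (n == 0) return(list())
  if (!is.finite(chunk_size)) return(list(seq_len(n)))
  starts <- seq(1L, n, by = as.integer(chunk_size))
  lapply(starts, function(s) seq(s, min(s + chunk_size - 1, n)))
}
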