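#' Fit a mass-univariate additive model by backfitting
#'
#' Estimates `y = f_1(x_1) + ... + f_m(x_m) + e` for every observation
#' column of `Y`, with one smoother per design column. Components are
#' estimated by the backfitting algorithm: cyclically, each smoother is
#' refitted to the partial residual of its covariate (the response minus all
#' other components), and every component is kept mean-centered so the
#' additive decomposition is identifiable; the constant is carried by the
#' intercept term. Iteration stops per observation when the largest absolute
#' change of any component falls below `tol`, or after `max_iter` sweeps
#' (non-convergence is recorded in the returned object and raised as a
#' warning, never an error).
#'
#' With linear or polynomial smoothers each smoother fit is an ordinary
#' least-squares fit, and the backfitting fixed point coincides with the
#' joint linear model on the combined basis, so the result is equivalent to
#' [fit_glm()].
#'
#' @inheritParams fit_glm
#' @param smoothers A smoother or list of smoothers (recycled over columns);
#'   see [sm_linear()].
#' @param max_iter,tol Backfitting controls (see [spec_gam()]).
#' @return An object of class `nm_gam` with per-smoother coefficients, the
#'   fitted matrix, the degrees of freedom (sum of smoother dfs), and
#'   per-observation iteration counts and convergence flags.
#' @export
fit_gam <- function(X, Y, smoothers = sm_bspline(8), max_iter = 500,
                    tol = 1e-6, intercept = TRUE, chunk_size = Inf) {
  Y <- as_obs_matrix(Y)
  X <- as_design_matrix(X, nrow(Y))
  if (ncol(X) == 0) abort("additive model needs at least one design column")
  if (inherits(smoothers, "nm_smoother")) smoothers <- list(smoothers)
  smoothers <- rep_len(smoothers, ncol(X))
  m <- ncol(X); L <- nrow(Y); N <- ncol(Y)

  bases <- lapply(seq_len(m), function(j) smoother_basis(X[, j], smoothers[[j]]))
  # each smoother regression carries a local intercept; centering then
  # removes the constant so components stay identifiable
  qrs <- lapply(bases, function(b) qr(cbind(1, b$train)))
  for (j in seq_len(m)) {
    if (qrs[[j]]$rank < ncol(bases[[j]]$train) + 1) {
      abort(sprintf("smoother basis for design column %d is rank deficient", j))
    }
  }

  alpha0 <- if (intercept) colMeans(Y) else rep(0, N)
  coefs <- vector("list", m)
  centers <- vector("list", m)
  iters <- integer(N)
  converged <- logical(N)

  fitted <- matrix(NA_real_, L, N)
  for (idx in chunk_indices(N, chunk_size)) {
    res <- backfit_chunk(Y[, idx, drop = FALSE], alpha0[idx], bases, qrs,
                         max_iter, tol)
    fitted[, idx] <- res$fitted
    iters[idx] <- res$iters
    converged[idx] <- res$converged
    for (j in seq_len(m)) {
      if (is.null(coefs[[j]])) {
        coefs[[j]] <- matrix(NA_real_, nrow(res$coefs[[j]]), N)
        centers[[j]] <- numeric(N)
      }
      coefs[[j]][, idx] <- res$coefs[[j]]
      centers[[j]][idx] <- res$centers[[j]]
    }
  }
  if (!all(converged)) {
    warn(sprintf("backfitting did not converge for %d of %d observations within %d sweeps",
                 sum(!converged), N, max_iter))
  }
  structure(list(
    coef = coefs, centers = centers, alpha = alpha0, fitted = fitted,
    df = sum(vapply(bases, `[[`, numeric(1), "df")),
    bases = bases, smoothers = smoothers,
    iterations = iters, converged = converged,
    n_covariates = m, L = L, intercept = intercept
  ), class = c("nm_gam", "nm_stage_fit"))
}

# Backfitting for one block of observation columns.  All updates are
# columnwise, so results do not depend on how observations are chunked.
backfit_chunk <- function(Y, alpha, bases, qrs, max_iter, tol) {
  L <- nrow(Y); n <- ncol(Y); m <- length(bases)
  Rbase <- sweep(Y, 2, alpha)
  Fs <- lapply(seq_len(m), function(j) matrix(0, L, n))
  Ftot <- matrix(0, L, n)
  coefs <- lapply(seq_len(m), function(j) matrix(0, ncol(bases[[j]]$train) + 1, n))
  centers <- lapply(seq_len(m), function(j) numeric(n))
  active <- seq_len(n)
  iters <- integer(n); conv <- logical(n)
  it <- 0L
  while (length(active) && it < max_iter) {
    it <- it + 1L
    delta <- numeric(length(active))
    for (j in seq_len(m)) {
      P <- Rbase[, active, drop = FALSE] - Ftot[, active, drop = FALSE] +
        Fs[[j]][, active, drop = FALSE]
      cf <- qr.coef(qrs[[j]], P)
      fit <- mm_bycol(cbind(1, bases[[j]]$train), cf)
      cm <- colMeans(fit)
      Fnew <- sweep(fit, 2, cm)
      delta <- pmax(delta, apply(abs(Fnew - Fs[[j]][, active, drop = FALSE]), 2, max))
      Ftot[, active] <- Ftot[, active, drop = FALSE] -
        Fs[[j]][, active, drop = FALSE] + Fnew
      Fs[[j]][, active] <- Fnew
      coefs[[j]][, active] <- cf
      centers[[j]][active] <- cm
    }
    iters[active] <- it
    done <- delta < tol
    conv[active[done]] <- TRUE
    active <- active[!done]
  }
  list(fitted = sweep(Ftot, 2, alpha, `+`), coefs = coefs, centers = centers,
       iters = iters, converged = conv)
}

# Evaluate one additive component (mean-centered) at new covariate values.
gam_component <- function(object, j, z) {
  B <- cbind(1, object$bases[[j]]$eval(z))
  sweep(B %*% object$coef[[j]], 2, object$centers[[j]])
}

#' @export
predict.nm_gam <- function(object, newdata, ...) {
  X <- as_design_matrix(newdata, NULL)
  if (ncol(X) != object$n_covariates) {
    abort(sprintf("newdata has %d columns; model was trained on %d",
                  ncol(X), object$n_covariates))
  }
  out <- matrix(rep(object$alpha, each = nrow(X)), nrow(X))
  for (j in seq_len(object$n_covariates)) {
    out <- out + gam_component(object, j, X[, j])
  }
  out
}
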