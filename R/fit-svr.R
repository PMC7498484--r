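#' Fit mass-univariate epsilon-insensitive support vector regression
#'
#' For each observation column, finds the function with at most
#' `eps`-deviation from the data that is as flat as possible in the kernel
#' feature space, with the box constraint `cost` trading flatness against
#' violations of the tube. The fitted function has the kernel expansion
#' `f(x) = sum_l beta_l k(x_l, x) + b` over the support vectors. Unlike the
#' linear and additive families, the kernel couples design columns, so
#' interactions are modeled implicitly.
#'
#' The quadratic program is solved by libsvm (via \pkg{e1071}) without any
#' internal rescaling of inputs. The effective degrees of freedom per
#' observation are estimated as the number of marginal support vectors —
#' dual coefficients strictly inside the box, `0 < |beta_l| < cost` — with a
#' floor of 1; a trace-based estimate of the kernel smoother is available as
#' an alternative through `df_method = "trace"`.
#'
#' @inheritParams fit_glm
#' @param kernel `"rbf"` (`k(u,v) = exp(-gamma ||u - v||^2)`) or
#'   `"polynomial"` (`k(u,v) = (u.v + coef0)^degree`).
#' @param eps,cost Tube half-width and box constraint.
#' @param gamma,degree,coef0 Kernel parameters.
#' @param df_method `"marginal_sv"` (default) or `"trace"`.
#' @return An object of class `nm_svr`: per-observation dual coefficients,
#'   support-vector indices and bias, the fitted matrix, and a
#'   per-observation `df` vector.
#' @export
fit_svr <- function(X, Y, kernel = c("rbf", "polynomial"), eps = 0.1,
                    cost = 1, gamma = 1, degree = 3, coef0 = 1,
                    df_method = c("marginal_sv", "trace"),
                    chunk_size = Inf) {
  kernel <- match.arg(kernel)
  df_method <- match.arg(df_method)
  Y <- as_obs_matrix(Y)
  X <- as_design_matrix(X, nrow(Y))
  if (ncol(X) == 0) abort("SVR needs at least one design column")
  if (eps < 0 || cost <= 0 || gamma <= 0) {
    abort("SVR hyperparameters out of range")
  }
  L <- nrow(Y); N <- ncol(Y)
  degenerate_X <- all(apply(X, 2, function(v) max(v) == min(v)))
  K <- svr_kernel_matrix(X, X, kernel, gamma, degree, coef0)
  fits <- vector("list", N)
  fitted <- matrix(NA_real_, L, N)
  df <- numeric(N)
  for (i in seq_len(N)) {
    y <- Y[, i]
    if (degenerate_X || max(y) == min(y)) {
      # constant design or constant response: the flattest function is the
      # (tube-censored) mean
      fits[[i]] <- list(constant = TRUE, value = mean(y))
      fitted[, i] <- mean(y)
      df[i] <- 1
      next
    }
    m <- e1071::svm(X, y, type = "eps-regression",
                    kernel = if (kernel == "rbf") "radial" else "polynomial",
                    gamma = if (kernel == "rbf") gamma else 1,
                    degree = degree, coef0 = coef0,
                    cost = cost, epsilon = eps, scale = FALSE,
                    fitted = FALSE)
    if (is.null(m$coefs) || length(m$index) == 0 || all(m$index == 0)) {
      # the tube absorbs every point: the flattest feasible function is the
      # constant at the bias
      fits[[i]] <- list(constant = TRUE, value = -m$rho)
      fitted[, i] <- -m$rho
      df[i] <- 1
      next
    }
    beta <- drop(m$coefs)
    fits[[i]] <- list(constant = FALSE, index = m$index, coefs = beta,
                      rho = m$rho)
    fitted[, i] <- drop(K[, m$index, drop = FALSE] %*% beta) - m$rho
    df[i] <- if (df_method == "marginal_sv") {
      max(1, sum(abs(beta) > 0 & abs(beta) < cost * (1 - 1e-8)))
    } else {
      sv <- m$index
      Ksv <- K[sv, sv, drop = FALSE]
      max(1, sum(diag(Ksv %*% pseudoinverse(Ksv + diag(1e-8, length(sv))))))
    }
  }
  structure(list(
    fits = fits, fitted = fitted, df = df,
    kernel = kernel, eps = eps, cost = cost, gamma = gamma,
    degree = degree, coef0 = coef0, X_train = X,
    n_covariates = ncol(X), L = L
  ), class = c("nm_svr", "nm_stage_fit"))
}

#' @export
stage_df.nm_svr <- function(fit) fit$df

#' @export
predict.nm_svr <- function(object, newdata, ...) {
  X <- as_design_matrix(newdata, NULL)
  if (ncol(X) != object$n_covariates) {
    abort(sprintf("newdata has %d columns; model was trained on %d",
                  ncol(X), object$n_covariates))
  }
  K <- svr_kernel_matrix(X, object$X_train, object$kernel, object$gamma,
                         object$degree, object$coef0)
  out <- matrix(NA_real_, nrow(X), length(object$fits))
  for (i in seq_along(object$fits)) {
    f <- object$fits[[i]]
    out[, i] <- if (f$constant) f$value else {
      drop(K[, f$index, drop = FALSE] %*% f$coefs) - f$rho
    }
  }
  out
}

# Kernel Gram matrix between row sets A and B.
svr_kernel_matrix <- function(A, B, kernel, gamma, degree, coef0) {
  if (kernel == "rbf") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    exp(-gamma * d2)
  } else {
    (tcrossprod(A, B) + coef0)^degree
  }
}
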