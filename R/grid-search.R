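#' Hyperparameter grid search for SVR
#'
#' Samples `H` hyperparameter combinations from the given ranges, fits each
#' on a random subset `G` of the observations (two-stage, with the given
#' corrector), and selects the combination minimizing the chosen metric
#' summed over the subset, with each observation's contribution weighted by
#' the inverse of its variance to absorb the large between-observation
#' variability of imaging data. Only observations with variance at least
#' `sigma_min` are eligible, which keeps near-constant background locations
#' out of the subset. The subset is re-drawn `iterations` times and scores
#' averaged to reduce selection bias. Ties are broken toward the smaller
#' `cost`, then the smaller `gamma`.
#'
#' @inheritParams fit_two_stage
#' @param space Named list over any of `cost`, `gamma`, `eps`: a length-2
#'   numeric range to search, or a scalar to hold fixed.
#' @param sampling `"deterministic-linear"`, `"deterministic-log"` (each
#'   searched parameter gets `floor(H^(1/P))` grid points, combined
#'   factorially) or `"random"` (`H` uniform draws, seeded).
#' @param H Number of combinations to aim for.
#' @param subset_size Number of observations per subset `G`.
#' @param metric `"mse"` (residual sum of squares), `"ftest"` (p-value of
#'   the nested-model F-test) or `"mallows_cp"` (noise variance taken from
#'   the most complex combination in the space).
#' @param iterations Number of subset re-draws.
#' @param sigma_min Minimum observation variance for eligibility.
#' @param seed Integer seed governing sampling and subset draws.
#' @param kernel,corrector_spec Passed through to [spec_svr()] /
#'   [fit_two_stage()].
#' @return A list with `best` (an [spec_svr()] spec) and `scores` (a tibble
#'   of combinations and averaged weighted scores).
#' @export
grid_search_svr <- function(Y, design, space = list(cost = c(0.1, 100), gamma = c(0.01, 10)),
                            sampling = c("deterministic-log", "deterministic-linear", "random"),
                            H = 9, subset_size = 20, metric = c("mse", "ftest", "mallows_cp"),
                            iterations = 1, sigma_min = 0, seed = 1,
                            kernel = "rbf", corrector_spec = spec_glm(1)) {
  sampling <- match.arg(sampling)
  metric <- match.arg(metric)
  Y <- as_obs_matrix(Y)
  stopifnot(H >= 1, subset_size >= 1, iterations >= 1)
  sigma <- apply(Y, 2, var)
  eligible <- which(sigma >= sigma_min & sigma > 0)
  if (length(eligible) == 0) abort("no observations with variance >= sigma_min")

  combos <- sample_combinations(space, sampling, H, seed)
  defaults <- list(cost = 1, gamma = 1, eps = 0.1)
  get_par <- function(row, p) if (p %in% names(combos)) combos[[p]][row] else
    if (p %in% names(space)) space[[p]][1] else defaults[[p]]
  n_combo <- nrow(combos)

  # noise variance for Mallows's Cp: residual variance of the most complex
  # combination in the space (largest cost, then largest gamma)
  complexity_rank <- order(vapply(seq_len(n_combo), get_par, numeric(1), p = "cost"),
                           vapply(seq_len(n_combo), get_par, numeric(1), p = "gamma"))
  largest <- tail(complexity_rank, 1)

  set.seed(seed + 1L)
  scores <- matrix(0, n_combo, iterations)
  for (it in seq_len(iterations)) {
    G <- if (length(eligible) <= subset_size) eligible else
      sort(sample(eligible, subset_size))
    fits <- lapply(seq_len(n_combo), function(r) {
      sp <- spec_svr(kernel = kernel, eps = get_par(r, "eps"),
                     cost = get_par(r, "cost"), gamma = get_par(r, "gamma"))
      fit_two_stage(Y[, G, drop = FALSE], design, corrector_spec, sp)
    })
    s2 <- if (metric == "mallows_cp") {
      f <- fits[[largest]]
      colSums(f$residuals^2) / pmax(f$L - f$df_correctors - f$df_predictors, 1)
    } else NULL
    for (r in seq_len(n_combo)) {
      f <- fits[[r]]
      ti <- switch(metric,
        mse = colSums(f$residuals^2),
        ftest = {
          ss_res <- colSums((f$Y - f$fitted_corrector)^2)
          ss_full <- colSums(f$residuals^2)
          f_nested(ss_res, ss_full, f$df_correctors + f$df_predictors,
                   f$df_correctors, f$L)$p
        },
        mallows_cp = colSums(f$residuals^2) / pmax(s2, .Machine$double.eps) -
          f$L + 2 * (f$df_correctors + f$df_predictors))
      scores[r, it] <- sum(ti / sigma[G])
    }
  }
  avg <- rowMeans(scores)
  ord <- order(avg,
               vapply(seq_len(n_combo), get_par, numeric(1), p = "cost"),
               vapply(seq_len(n_combo), get_par, numeric(1), p = "gamma"))
  best_row <- ord[1]
  best <- spec_svr(kernel = kernel, eps = get_par(best_row, "eps"),
                   cost = get_par(best_row, "cost"),
                   gamma = get_par(best_row, "gamma"))
  tab <- as_tibble(combos)
  tab$score <- avg
  list(best = best, scores = tab)
}

sample_combinations <- function(space, sampling, H, seed) {
  searched <- names(space)[vapply(space, length, integer(1)) == 2]
  if (length(searched) == 0) return(data.frame(row.names = 1))
  if (sampling == "random") {
    set.seed(seed)
    out <- lapply(space[searched], function(rg) runif(H, rg[1], rg[2]))
    return(as.data.frame(out))
  }
  npts <- max(1L, floor(H^(1 / length(searched))))
  grids <- lapply(space[searched], function(rg) {
    if (sampling == "deterministic-log") {
      if (any(rg <= 0)) abort("logarithmic sampling needs positive ranges")
      exp(seq(log(rg[1]), log(rg[2]), length.out = npts))
    } else {
      seq(rg[1], rg[2], length.out = npts)
    }
  })
  expand.grid(grids)
}
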