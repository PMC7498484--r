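test_that("with no correctors the predictor is fitted to mean-centered data", {
  set.seed(21)
  L <- 30
  x <- runif(L, 0, 2)
  y <- 5 + 0.8 * x + rnorm(L, 0, 0.1)
  d <- list(XC = matrix(0, L, 0), XP = cbind(x))
  fit <- fit_two_stage(cbind(y), d, spec_glm(1), spec_glm(1))
  expect_equal(fit$df_correctors, 0)
  expect_equal(drop(fit$fitted_corrector), rep(mean(y), L))
  ref <- fit_glm(cbind(x), y - mean(y), degrees = 1)
  expect_equal(fit$predictor$fitted, ref$fitted, tolerance = 1e-10)
})

test_that("two-stage equals the joint fit when covariates are orthogonalized", {
  set.seed(22)
  tab <- rand_covariates(50, seed = 22)
  tab <- preprocess_covariates(tab, "orthogonalize")
  d <- split_by_role(tab, "adcsf")
  Y <- matrix(rnorm(50 * 6), 50, 6)
  fit <- fit_two_stage(Y, d, spec_glm(1), spec_glm(1))
  joint <- fit_glm(cbind(d$XC, d$XP), Y, degrees = 1)
  expect_equal(fit$fitted, joint$fitted, tolerance = 1e-8)
  # concatenated coefficients agree with the joint solve
  cc <- fit$corrector$coef[-1, , drop = FALSE]   # drop intercept row
  pc <- fit$predictor$coef[-1, , drop = FALSE]
  expect_equal(unname(rbind(cc, pc)), unname(joint$coef[-1, , drop = FALSE]),
               tolerance = 1e-8)
})

test_that("corrector residuals are orthogonal to the corrector design", {
  set.seed(23)
  ph <- generate_phantom(small_phantom_spec(seed = 23))
  Y <- masked_data(ph$obs)[, 1:50]
  d <- split_by_role(ph$covariates, "adcsf")
  fit <- fit_two_stage(Y, d, spec_glm(c(2, 1)), spec_gam(sm_bspline(5)))
  R <- fit$Y - fit$fitted_corrector
  cors <- abs(crossprod(scale(d$XC), scale(R))) / (nrow(R) - 1)
  expect_lt(max(cors), 1e-6)
})

test_that("predictions on the training covariates reproduce stored fits", {
  set.seed(24)
  tab <- rand_covariates(40, seed = 24)
  d <- split_by_role(tab, "adcsf")
  Y <- matrix(rnorm(40 * 3), 40, 3)
  fit <- fit_two_stage(Y, d, spec_glm(c(2, 1)), spec_glm(2))
  pred <- predict(fit, tab)
  expect_equal(unname(pred), unname(fit$fitted), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_false(attr(pred, "extrapolated"))
  # extrapolation is allowed but flagged
  tab2 <- tab; tab2$adcsf[1] <- 5
  expect_warning(p2 <- predict(fit, tab2), "extrapolat")
  expect_true(attr(p2, "extrapolated"))
})

test_that("curve evaluation spans the training range with the line a GLM implies", {
  set.seed(25)
  L <- 30
  x <- runif(L, 0, 1)
  y <- 2 + 3 * x + rnorm(L, 0, 0.01)
  d <- list(XC = matrix(0, L, 0), XP = cbind(x))
  fit <- fit_two_stage(cbind(y), d, spec_glm(1), spec_glm(1))
  cs <- eval_curves(fit, T = 5)
  expect_equal(length(cs$grid), 5)
  expect_equal(range(cs$grid), range(x))
  b <- fit$predictor$coef
  expect_equal(cs$curves[1, ], b[1, 1] + b[2, 1] * cs$grid, tolerance = 1e-10)
})

test_that("additive-model curves equal the sum of per-smoother components", {
  set.seed(26)
  L <- 80
  tab <- rand_covariates(L, seed = 26)
  d <- split_by_role(tab, "adcsf")
  y <- 0.5 * tab$adcsf^2 - 0.01 * tab$age + rnorm(L, 0, 0.1)
  fit <- fit_two_stage(cbind(y), d, spec_glm(1), spec_gam(sm_bspline(6)))
  cs <- eval_curves(fit, T = 20)
  comp <- nlmorph:::gam_component(fit$predictor, 1, cs$grid)
  expect_equal(cs$curves[1, ], drop(comp) + fit$predictor$alpha[1],
               tolerance = 1e-10)
})

test_that("mixed-family stages compose and report their degrees of freedom", {
  set.seed(27)
  tab <- rand_covariates(60, seed = 27)
  d <- split_by_role(tab, "adcsf")
  Y <- matrix(rnorm(60 * 2), 60, 2)
  fit <- fit_two_stage(Y, d, spec_gam(list(sm_bspline(4), sm_linear())),
                       spec_svr(eps = 0.2, cost = 5, gamma = 1))
  expect_equal(fit$df_correctors, 5)
  expect_true(all(fit$df_predictors >= 1))
  expect_true(all(is.finite(fit$fitted)))
})

test_that("two-stage results are chunk-invariant end to end", {
  set.seed(28)
  tab <- rand_covariates(40, seed = 28)
  d <- split_by_role(tab, "adcsf")
  Y <- matrix(rnorm(40 * 13), 40, 13)
  full <- fit_two_stage(Y, d, spec_glm(c(2, 1)), spec_glm(2))
  for (cs in c(1, 7, 13)) {
    ch <- fit_two_stage(Y, d, spec_glm(c(2, 1)), spec_glm(2), chunk_size = cs)
    expect_identical(ch$fitted, full$fitted)
    expect_identical(ch$residuals, full$residuals)
  }
})
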