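test_that("error and determination metrics follow their definitions", {
  y <- c(1, 2, 3); yhat <- c(1, 1, 3)
  expect_equal(mse(y, yhat), 1)
  expect_equal(r2(y, yhat), 0.5)          # SS_res = 1, SS_y = 2
  expect_equal(mse(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_true(is.na(r2(rep(1, 3), c(1, 1, 2))))
})

test_that("AIC reduces to its closed form and is linear in the parameter count", {
  expect_equal(aic(1 / (2 * pi), 1, 1), 3)
  m <- 0.37; L <- 23
  expect_equal(aic(m, 7, L) - aic(m, 4, L), 6)
  expect_warning(v <- aic(0, 2, 10), "-Inf")
  expect_equal(v, -Inf)
})

test_that("AIC prefers the true small model on null data", {
  set.seed(33)
  L <- 50
  wins <- replicate(500, {
    x <- runif(L)
    y <- 1 + x + rnorm(L)
    small <- fit_glm(cbind(x), y, degrees = 1)
    big <- fit_glm(cbind(x), y, degrees = 4)
    a_small <- aic(sum((y - small$fitted)^2) / L, 2, L)
    a_big <- aic(sum((y - big$fitted)^2) / L, 5, L)
    a_small < a_big
  })
  expect_gte(mean(wins), 0.8)
})

test_that("the nested F statistic matches hand computation and the F law", {
  ft <- f_test(ss_res = 20, ss_full = 10, df_full = 2, df_restricted = 1, L = 10)
  expect_equal(ft$f_score, 8)
  expect_equal(ft$p_value, pf(8, 1, 8, lower.tail = FALSE))
  ft0 <- f_test(10, 10, 2, 1, 10)
  expect_equal(ft0$f_score, 0)
  expect_equal(ft0$p_value, 1)
  expect_warning(ftz <- f_test(5, 0, 2, 1, 10), "SS_full")
  expect_equal(ftz$p_value, 0)
  expect_error(f_test(5, 4, 2, 2, 10), "df_full")
})

test_that("F scores are nonnegative and p decreases monotonically in f", {
  set.seed(34)
  ssr <- runif(50, 1, 10)
  ssf <- ssr * runif(50, 0.2, 1)
  ft <- f_test(ssr, ssf, 3, 1, 40)
  expect_true(all(ft$f_score >= 0))
  o <- order(ft$f_score)
  expect_true(all(diff(ft$p_value[o]) <= 1e-15))
})

test_that("roughness vanishes for lines and matches the quadratic closed form", {
  grid <- seq(0, 1, length.out = 400)
  lin <- 2 - 3 * grid
  expect_equal(curve_abruptness(lin, grid), 0, tolerance = 1e-18)
  expect_equal(prss(lin, grid, mse_value = 1.7, gamma = 10), 1.7)
  # f = x^2 has f'' = 2, so the squared-roughness integral over [0,1] is 4
  quad <- grid^2
  expect_equal(curve_abruptness(quad, grid), 4, tolerance = 0.01)
  expect_equal(prss(quad, grid, 0.5, gamma = 2), 0.5 + 2 * curve_abruptness(quad, grid))
  expect_equal(prss(quad, grid, 0.5, gamma = 0), 0.5)
})

test_that("PRSS never falls below the residual error", {
  set.seed(35)
  grid <- seq(0, 2, length.out = 50)
  for (i in 1:20) {
    curve <- cumsum(rnorm(50, 0, 0.1))
    m <- runif(1, 0, 5); g <- runif(1, 0, 2)
    expect_gte(prss(curve, grid, m, g), m)
  }
})

test_that("variance normalization guards against flat curves", {
  grid <- seq(0, 1, length.out = 20)
  expect_true(is.na(vnprss(1, rep(2, 20), grid, ybar = 2)))
  curve <- grid
  expect_equal(vnprss(3, curve, grid, ybar = 0), 3 / sum(curve^2))
})

test_that("statistical maps vectorize the scalar metrics per observation", {
  set.seed(36)
  L <- 30
  tab <- rand_covariates(L, seed = 36)
  d <- split_by_role(tab, "adcsf")
  Y <- matrix(rnorm(L * 3), L, 3)
  fit <- fit_two_stage(Y, d, spec_glm(1), spec_glm(2))
  m_mse <- make_stat_map(fit, "mse")
  m_r2 <- make_stat_map(fit, "r2")
  m_f <- make_stat_map(fit, "ftest")
  for (i in 1:3) {
    expect_equal(m_mse$values[i], mse(Y[, i], fit$fitted[, i]))
    expect_equal(m_r2$values[i], r2(Y[, i], fit$fitted[, i]))
    or <- f_test(sum((Y[, i] - fit$fitted_corrector[, i])^2),
                 sum((Y[, i] - fit$fitted[, i])^2),
                 fit$df_correctors + fit$df_predictors,
                 fit$df_correctors, L)
    expect_equal(m_f$values[i], or$f_score)
    expect_equal(m_f$p_value[i], or$p_value)
  }
  expect_equal(m_f$significance, 1 - m_f$p_value)
})

test_that("cluster-extent filtering drops small components and keeps real signal", {
  # a 2-voxel blob cannot survive an extent threshold of 8
  ph <- generate_phantom(small_phantom_spec(seed = 37, L = 60))
  Y <- masked_data(ph$obs)
  d <- split_by_role(ph$covariates, "adcsf")
  fit <- fit_two_stage(Y, d, spec_glm(c(2, 1)), spec_glm(2))
  map <- make_stat_map(fit, "ftest", obs = ph$obs)
  thr <- threshold_map(map, p_threshold = 0.001, extent = 4)
  expect_true(all(thr$cluster_sizes >= 4))
  # the quadratic region (8 voxels in the small phantom) must survive
  quad <- match(ph$region_index[[2]], which(ph$obs$mask))
  expect_gt(mean(thr$keep[quad]), 0.5)
  # extent above any plausible null blob size kills noise-only voxels
  thr_big <- threshold_map(map, p_threshold = 0.001, extent = 100)
  expect_equal(sum(thr_big$keep), 0)
})

test_that("false positives rarely form large clusters on a null phantom", {
  null_spec <- phantom_spec(L = 40, shape = c(10, 10, 10), regions = list(),
                            sigma = 0.4, seed = 38)
  counts <- vapply(1:5, function(s) {
    sp <- null_spec; sp$seed <- 38 + s
    ph <- generate_phantom(sp)
    Y <- masked_data(ph$obs)
    d <- split_by_role(ph$covariates, "adcsf")
    fit <- fit_two_stage(Y, d, spec_glm(c(2, 1)), spec_glm(2))
    map <- make_stat_map(fit, "ftest", obs = ph$obs)
    threshold_map(map, p_threshold = 0.001, extent = 100)$n_clusters
  }, numeric(1))
  expect_true(all(counts == 0))
})

test_that("connected-component labeling respects face connectivity", {
  vol <- array(FALSE, c(4, 4, 4))
  vol[1:2, 1, 1] <- TRUE          # one 2-voxel component
  vol[4, 4, 4] <- TRUE            # isolated voxel
  vol[1, 3, 1] <- TRUE            # diagonal from the first: separate
  lab <- nlmorph:::label_components6(vol)
  expect_equal(max(lab), 3)
  expect_equal(lab[1, 1, 1], lab[2, 1, 1])
  expect_true(lab[1, 3, 1] != lab[1, 1, 1])
})
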