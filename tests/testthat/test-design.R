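test_that("normalize scales columns to unit norm and rejects zero columns", {
  tab <- tibble::tibble(a = c(3, 0, 4, 0), b = c(1, 1, 1, 1))
  out <- preprocess_covariates(tab, "normalize")
  expect_equal(unname(sqrt(colSums(as.matrix(out)^2))), c(1, 1))
  expect_equal(out$a, c(3, 0, 4, 0) / 5)
  tab$z <- 0
  expect_error(preprocess_covariates(tab, "normalize"), "zero-norm")
})

test_that("orthogonalization residualizes in column order and errors on collinearity", {
  # age and age^2 on a tiny grid: the second column must equal the
  # least-squares residual of age^2 on {1, age} (normal-equations oracle)
  age <- c(1, 2, 3, 4)
  tab <- tibble::tibble(age = age, age2 = age^2)
  out <- preprocess_covariates(tab, "orthogonalize")
  oracle <- residuals(lm(age2 ~ age, data = tab))
  expect_equal(out$age2, unname(oracle), tolerance = 1e-10)
  expect_equal(out$age, age - mean(age), tolerance = 1e-12)

  dup <- tibble::tibble(a = rnorm(10), b = 0)
  dup$b <- 2 * dup$a
  expect_error(preprocess_covariates(dup, "orthogonalize"), "'b'")
})

test_that("orthonormalize is idempotent on centered orthonormal columns", {
  set.seed(1)
  Q <- qr.Q(qr(scale(matrix(rnorm(30), 10, 3), scale = FALSE)))
  out <- preprocess_covariates(as.data.frame(Q), "orthonormalize")
  expect_equal(as.matrix(out), Q, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("orthogonalized outputs have diagonal Gram matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 4), 25, 4)
    out <- as.matrix(preprocess_covariates(as.data.frame(X), "orthogonalize"))
    G <- crossprod(out)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
})

test_that("unit contrast yields the expected null-contrast projector", {
  ct <- build_contrast(c(0, 0, 1))
  expect_equal(ct$C0, diag(c(1, 1, 0)), tolerance = 1e-12)
  # orthonormal columns: C C# is a symmetric projector with trace P
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  ct2 <- build_contrast(Q)
  P <- Q %*% ct2$pinv
  expect_equal(P, t(P), tolerance = 1e-10)
  expect_equal(sum(diag(P)), 2, tolerance = 1e-10)
  expect_error(build_contrast(matrix(0, 3, 1)), "zero")
})

test_that("pseudoinverse agrees with an independent SVD-based oracle", {
  set.seed(3)
  C <- matrix(rnorm(8), 4, 2)
  ct <- build_contrast(C)
  expect_equal(ct$pinv, MASS::ginv(C), tolerance = 1e-10)
  expect_lt(max(abs(ct$C0 %*% C)), 1e-10)
  expect_lt(max(abs(ct$C0 %*% ct$C0 - ct$C0)), 1e-10)
})

test_that("null-contrast invariants hold over random full-rank contrasts", {
  set.seed(4)
  for (i in 1:100) {
    M <- sample(3:6, 1)
    P <- sample(seq_len(M - 1), 1)
    C <- matrix(rnorm(M * P), M, P)
    ct <- build_contrast(C)
    expect_lt(max(abs(ct$C0 %*% C)), 1e-8)
    expect_lt(max(abs(ct$C0 %*% ct$C0 - ct$C0)), 1e-8)
  }
})

test_that("design split selects predictor columns and records kept correctors", {
  tab <- rand_covariates(20, seed = 5)
  d <- split_by_role(tab, "adcsf")
  X <- as.matrix(tab)
  expect_equal(unname(d$XP[, 1]), tab$adcsf)
  expect_equal(unname(d$XC), unname(X[, 1:2]), tolerance = 1e-12)
  expect_equal(d$kept_correctors, c(1L, 2L))
  expect_error(split_design(tab[, 1:2], build_contrast(c(0, 0, 1))),
               "3 rows")
})

test_that("subspaces are orthogonal exactly when covariate columns are", {
  set.seed(6)
  Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3))) # orthogonal columns
  d <- split_design(as.data.frame(Q), build_contrast(c(0, 0, 1)))
  expect_lt(max(abs(crossprod(d$XC, d$XP))), 1e-8)

  X <- matrix(rnorm(30 * 3), 30, 3) + 1      # correlated columns
  d2 <- split_design(as.data.frame(X), build_contrast(c(0, 0, 1)))
  cross <- crossprod(d2$XC, d2$XP)
  oracle <- t(X %*% build_contrast(c(0, 0, 1))$C0[, 1:2]) %*% (X %*% c(0, 0, 1))
  expect_gt(max(abs(cross)), 1e-4)
  expect_equal(unname(cross), unname(oracle), tolerance = 1e-10)
})

test_that("projector split reassembles the design for full-rank contrasts", {
  set.seed(7)
  X <- matrix(rnorm(15 * 4), 15, 4)
  C <- matrix(rnorm(8), 4, 2)
  ct <- build_contrast(C)
  expect_equal(X %*% C %*% ct$pinv + X %*% ct$C0, X, tolerance = 1e-10)
})

test_that("covariate tables reject malformed input", {
  expect_error(as_covariate_table(data.frame(a = 1)), "2 subjects")
  expect_error(as_covariate_table(data.frame(a = c(1, NA))), "missing")
  expect_error(as_covariate_table(data.frame(a = c("x", "y"))), "non-numeric")
})
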