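fake_map <- function(values, metric = "ftest") {
  structure(list(values = values, metric = metric, p_value = NULL,
                 geometry = NULL, mask = NULL), class = "nm_stat_map")
}

test_that("pairwise map algebra follows its definitions", {
  a <- fake_map(c(1, 2, 3)); b <- fake_map(c(1, 2, 3))
  expect_equal(combine_maps(list(a, b), "diff")$values, c(0, 0, 0))
  expect_equal(combine_maps(list(a, b), "absdiff")$values, c(0, 0, 0))
  expect_equal(combine_maps(list(a, b), "se")$values, c(0, 0, 0))
  cc <- fake_map(c(2, 0, 5))
  d1 <- combine_maps(list(a, cc), "diff")$values
  d2 <- combine_maps(list(cc, a), "diff")$values
  expect_equal(d1, -d2)                              # antisymmetry
  expect_equal(combine_maps(list(a, cc), "se")$values, d1^2)
  expect_error(combine_maps(list(a, b, cc), "diff"), "exactly 2")
})

test_that("rgb composites rescale each channel into the unit interval", {
  maps <- list(fake_map(c(0, 5, 10)), fake_map(c(-1, 0, 1)), fake_map(c(2, 2, 4)))
  rgb <- combine_maps(maps, "rgb")$values
  expect_equal(dim(rgb), c(3, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  expect_equal(rgb[, 1], c(0, 0.5, 1))
})

test_that("the best map is the per-observation argmax with low-index ties", {
  maps <- list(fake_map(c(2, 9)), fake_map(c(5, 9)), fake_map(c(3, 1)))
  best <- combine_maps(maps, "best")
  expect_equal(best$values, c(2, 1))   # ties at observation 2 go to model 1
  # lower-is-better polarity flips the winner
  mse_maps <- lapply(maps, function(m) fake_map(m$values, "mse"))
  expect_equal(combine_maps(mse_maps, "best")$values, c(1, 3))
  # brute-force argmax oracle on a random panel
  set.seed(39)
  vals <- replicate(4, runif(10), simplify = FALSE)
  got <- combine_maps(lapply(vals, fake_map), "best")$values
  oracle <- apply(do.call(cbind, vals), 1, which.max)
  expect_equal(got, oracle)
  expect_error(combine_maps(list(fake_map(1:3, "mse"), fake_map(1:3, "ftest")),
                            "best"), "mixed")
})

test_that("the derivative-weighted distance obeys its closed forms", {
  x <- sin(seq(0, 2, length.out = 40))
  expect_equal(curve_similarity(x, x), 0)
  # constant offset: only the order-0 term contributes
  T <- 40; cst <- 0.7
  expect_equal(curve_similarity(x, x + cst, normalize = FALSE),
               0.2 * cst * sqrt(T), tolerance = 1e-10)
  expect_equal(curve_similarity(x, x + cst, normalize = TRUE), 0.2 * cst,
               tolerance = 1e-10)
  expect_error(curve_similarity(x[1:2], x[1:2]), "grid points")
  expect_error(curve_similarity(x, x[1:10]), "share the grid")
})

test_that("the distance is a pseudometric on random curve triples", {
  set.seed(40)
  for (i in 1:25) {
    cm <- matrix(rnorm(3 * 20), 3, 20)
    d12 <- curve_similarity(cm[1, ], cm[2, ])
    d13 <- curve_similarity(cm[1, ], cm[3, ])
    d23 <- curve_similarity(cm[2, ], cm[3, ])
    expect_gte(d12, 0)
    expect_equal(d12, curve_similarity(cm[2, ], cm[1, ]))
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("requesting one cluster per curve returns singletons", {
  set.seed(41)
  cm <- matrix(rnorm(5 * 30), 5, 30)
  res <- cluster_curves(cm, 5)
  expect_equal(res$labels, 1:5)
  expect_equal(nrow(res$merges), 0)
  expect_error(cluster_curves(cm, 6), "n_clusters")
})

test_that("well-separated curve families are recovered exactly", {
  cs <- generate_curve_set(c("linear", "sigmoid"), n_per_family = 20,
                           noise = 0.01, seed = 42)
  res <- cluster_curves(cs$curves, 2)
  agree <- max(mean(res$labels == cs$labels), mean(res$labels == 3 - cs$labels))
  expect_equal(agree, 1)
})

test_that("the merge sequence matches a brute-force average-linkage oracle", {
  set.seed(43)
  cm <- matrix(rnorm(6 * 25), 6, 25)
  res <- cluster_curves(cm, 1, standardize = FALSE)
  D <- nlmorph:::sd_distance_matrix(cm)
  oracle <- brute_average_linkage(D, 1)
  expect_equal(as.matrix(res$merges), oracle$merges, ignore_attr = TRUE,
               tolerance = 1e-10)
  # heights also agree with the reference hierarchical clusterer
  h <- hclust(as.dist(D), method = "average")
  expect_equal(sort(res$merges$height), sort(h$height), tolerance = 1e-10)
})

test_that("cluster assignments are invariant under curve permutation", {
  cs <- generate_curve_set(c("linear", "quadratic", "sigmoid"),
                           n_per_family = 8, noise = 0.02, seed = 44)
  res <- cluster_curves(cs$curves, 3, standardize = FALSE)
  set.seed(45)
  perm <- sample(nrow(cs$curves$curves))
  res_p <- cluster_curves(cs$curves$curves[perm, ], 3, standardize = FALSE)
  # same partition up to label names
  tab <- table(res$labels[perm], res_p$labels)
  expect_equal(sum(tab > 0), 3)
})

test_that("silhouette separates tight groups and is near zero for random labels", {
  base <- sin(seq(0, 2, length.out = 30))
  tight <- rbind(matrix(rep(base, 5), 5, byrow = TRUE),
                 matrix(rep(base + 10 * seq(0, 2, length.out = 30), 5), 5,
                        byrow = TRUE))
  dg <- cluster_diagnostics(tight, rep(1:2, each = 5), standardize = FALSE)
  expect_gt(dg$silhouette_mean, 0.99)

  set.seed(46)
  hom <- matrix(rnorm(20 * 30, sd = 0.05) +
                  rep(base, each = 20), 20, 30)
  sils <- replicate(100, {
    cluster_diagnostics(hom, sample(rep(1:2, 10)), standardize = FALSE)$silhouette_mean
  })
  expect_lt(mean(abs(sils)), 0.1)
})

test_that("silhouette across cluster counts peaks at the generating number", {
  # amplitude carries family identity here, so clustering runs on raw curves
  cs <- generate_curve_set(c("linear", "quadratic", "sigmoid"),
                           n_per_family = 10, noise = 0.02, seed = 47)
  sil <- vapply(2:6, function(k) {
    cluster_curves(cs$curves, k, standardize = FALSE)$silhouette_mean
  }, numeric(1))
  expect_equal(which.max(sil) + 1, 3)
})

test_that("silhouettes agree with the reference implementation", {
  cs <- generate_curve_set(c("linear", "sigmoid"), n_per_family = 10,
                           noise = 0.02, seed = 63)
  res <- cluster_curves(cs$curves, 2)
  D <- nlmorph:::sd_distance_matrix(
    nlmorph:::standardize_curves(cs$curves$curves))
  ref <- cluster::silhouette(res$labels, dmatrix = D)
  dg <- cluster_diagnostics(cs$curves, res$labels)
  expect_equal(dg$silhouettes, unname(ref[, "sil_width"]), tolerance = 1e-10)
  expect_equal(dg$silhouette_mean, mean(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("singleton clusters contribute zero silhouette with a flag-safe path", {
  cm <- rbind(matrix(rnorm(4 * 20, sd = 0.01), 4, 20),
              10 + rnorm(20, sd = 0.01))
  dg <- cluster_diagnostics(cm, c(1, 1, 1, 1, 2), standardize = FALSE)
  expect_equal(dg$silhouettes[5], 0)
})
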