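test_that("a noiseless phantom is the exact ground-truth composition", {
  sp <- small_phantom_spec(seed = 55)
  sp$sigma <- 0
  ph <- generate_phantom(sp)
  ce <- sp$corrector_effects
  expected_bg <- sp$baseline + ce$age_slope * ph$covariates$age +
    ce$age2 * ph$covariates$age^2 + ce$sex * ph$covariates$sex
  bg_voxel <- setdiff(seq_len(prod(sp$shape)), unlist(ph$region_index))[1]
  expect_equal(ph$obs$data[, bg_voxel], expected_bg, tolerance = 1e-12)
  lin_voxel <- ph$region_index[[1]][1]
  expect_equal(ph$obs$data[, lin_voxel],
               expected_bg - 0.4 * ph$covariates$adcsf, tolerance = 1e-12)
})

test_that("voxels without signal are uncorrelated with the predictor", {
  sp <- phantom_spec(L = 80, shape = c(6, 6, 6), regions = list(), seed = 56)
  ph <- generate_phantom(sp)
  cors <- abs(cor(ph$covariates$adcsf, ph$obs$data))
  expect_lt(mean(cors), 2 / sqrt(sp$L))
  expect_gt(mean(cors < 2 / sqrt(sp$L)), 0.9)
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ph1 <- generate_phantom(small_phantom_spec(seed = 57), dir = d1)
  ph2 <- generate_phantom(small_phantom_spec(seed = 57), dir = d2)
  sums1 <- unname(tools::md5sum(ph1$files$images))
  sums2 <- unname(tools::md5sum(ph2$files$images))
  expect_identical(sums1, sums2)
  expect_identical(unname(tools::md5sum(ph1$files$covariates)),
                   unname(tools::md5sum(ph2$files$covariates)))
  ph3 <- generate_phantom(small_phantom_spec(seed = 58))
  expect_false(identical(ph1$obs$data, ph3$obs$data))
})

test_that("phantoms round-trip through the image reader bit for bit at storage precision", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(small_phantom_spec(seed = 59), dir = d)
  obs <- load_observations(ph$files$images)
  expect_equal(obs$data, ph$obs$data, tolerance = 1e-6)
  expect_equal(obs$mask, ph$obs$mask)
})

test_that("regions must stay disjoint and inside the volume", {
  vox <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  expect_error(phantom_spec(regions = list(
    list(voxels = vox, family = "linear", effect = 1),
    list(voxels = vox, family = "sigmoid", effect = 1))), "overlap")
  expect_error(phantom_spec(shape = c(4, 4, 4), regions = list(
    list(voxels = cbind(9, 1, 1), family = "linear", effect = 1))), "outside")
})

test_that("noise-free families are separated by construction", {
  cs <- generate_curve_set(c("linear", "sigmoid"), n_per_family = 6,
                           noise = 0, seed = 60)
  M <- cs$curves$curves
  D <- nlmorph:::sd_distance_matrix(M)
  within <- D[cs$labels == 1, cs$labels == 1]
  between <- D[cs$labels == 1, cs$labels == 2]
  expect_gt(min(between), max(within))
})

test_that("generator labels survive the clustering round trip at low noise", {
  cs <- generate_curve_set(c("linear", "quadratic", "sigmoid"),
                           n_per_family = 12, noise = 0.02, seed = 61)
  res <- cluster_curves(cs$curves, 3, standardize = FALSE)
  tab <- table(cs$labels, res$labels)
  expect_equal(sum(apply(tab, 1, max)), length(cs$labels))
})

test_that("splitting one homogeneous family yields weak silhouettes", {
  cs <- generate_curve_set("sigmoid", n_per_family = 24, noise = 0.05,
                           seed = 62)
  res <- cluster_curves(cs$curves, 2)
  expect_lt(res$silhouette_mean, 0.2)
})

test_that("stronger effects never weaken the region F statistic", {
  rates <- vapply(1:10, function(s) {
    fscore_for <- function(effect) {
      cube <- as.matrix(expand.grid(2:3, 2:3, 2:3))
      sp <- phantom_spec(L = 60, shape = c(6, 6, 6),
                         regions = list(list(voxels = cube,
                                             family = "quadratic",
                                             effect = effect)),
                         sigma = 0.4, seed = 100 + s)
      ph <- generate_phantom(sp)
      Y <- masked_data(ph$obs)
      des <- split_by_role(ph$covariates, "adcsf")
      fit <- fit_two_stage(Y, des, spec_glm(c(2, 1)), spec_glm(2))
      map <- make_stat_map(fit, "ftest")
      mean(map$values[match(ph$region_index[[1]], which(ph$obs$mask))])
    }
    fscore_for(-0.6) - fscore_for(-0.3)
  }, numeric(1))
  expect_true(all(rates >= 0))
})
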