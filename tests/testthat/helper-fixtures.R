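# Shared fixtures and independent oracles used across the suite.

rand_covariates <- function(L = 40, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    age = runif(L, 45, 75),
    sex = rbinom(L, 1, 0.5),
    adcsf = runif(L, 0, 2)
  )
}

# Independent normal-equations solve (never goes through fit_glm).
ls_oracle <- function(D, y) solve(crossprod(D), crossprod(D, y))

# Brute-force average-linkage agglomeration: recomputes every pairwise
# cluster linkage from the raw distance matrix at each step, with the same
# smallest-index tie-break contract as the implementation.
brute_average_linkage <- function(D, n_clusters) {
  N <- nrow(D)
  cl <- as.list(seq_len(N))
  merges <- NULL
  while (length(cl) > n_clusters) {
    best <- c(Inf, NA, NA, NA, NA)
    for (a in seq_len(length(cl) - 1)) {
      for (b in (a + 1):length(cl)) {
        lv <- mean(D[cl[[a]], cl[[b]]])
        lo <- min(min(cl[[a]]), min(cl[[b]]))
        hi <- max(min(cl[[a]]), min(cl[[b]]))
        better <- lv < best[1] - 1e-15 ||
          (abs(lv - best[1]) < 1e-15 &&
             (lo < best[2] || (lo == best[2] && hi < best[3])))
        if (better) best <- c(lv, lo, hi, a, b)
      }
    }
    merges <- rbind(merges, best[c(2, 3, 1)])
    cl[[best[4]]] <- c(cl[[best[4]]], cl[[best[5]]])
    cl[[best[5]]] <- NULL
  }
  colnames(merges) <- c("a", "b", "height")
  list(merges = merges, clusters = cl)
}

# Small phantom spec for fast pipeline tests.
small_phantom_spec <- function(seed = 42, L = 30) {
  cube <- function(o) as.matrix(expand.grid(o[1] + 0:1, o[2] + 0:1, o[3] + 0:1))
  phantom_spec(
    L = L, shape = c(8, 8, 8),
    regions = list(
      list(voxels = cube(c(2, 2, 2)), family = "linear", effect = -0.4),
      list(voxels = cube(c(5, 5, 5)), family = "quadratic", effect = -0.4)),
    sigma = 0.3, seed = seed)
}

pipeline_config <- function(dir, spec = small_phantom_spec()) {
  cfg <- default_config()
  cfg$paths$output <- dir
  cfg$paths$covariates <- file.path(dir, "phantom", "covariates.csv")
  cfg$paths$images <- file.path(dir, "phantom")
  cfg$phantom$L <- spec$L
  cfg$phantom$shape <- spec$shape
  cfg$phantom$sigma <- spec$sigma
  cfg$phantom$seed <- spec$seed
  cfg$inference$metrics <- c("ftest", "mse")
  cfg$clustering$model <- "glm2"
  cfg$clustering$n_clusters <- 2
  cfg
}
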