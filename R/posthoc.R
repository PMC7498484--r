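#' Combine statistical maps across models
#'
#' Reduces a list of per-observation maps from different fitting models to a
#' single comparison map: elementwise difference (`"diff"`, 2 maps),
#' absolute difference (`"absdiff"`), squared difference (`"se"`), a color
#' composite placing each of 3 maps in one min-max rescaled channel
#' (`"rgb"`), or the per-observation index of the best model (`"best"`,
#' 2+ maps) under the metric's polarity — higher is better for F scores,
#' R-squared and significance; lower is better for MSE, AIC, PRSS, VNPRSS
#' and p-values. Ties go to the lowest model index.
#'
#' @param maps List of `nm_stat_map`s (or plain numeric vectors) over the
#'   same observations.
#' @param kind One of `"diff"`, `"absdiff"`, `"se"`, `"rgb"`, `"best"`.
#' @param polarity `"higher"` or `"lower"`; required for `"best"` when the
#'   maps are plain vectors or carry mixed metrics.
#' @return An object of class `nm_comparison`; `values` is a vector
#'   (diff/absdiff/se/best) or an N x 3 matrix in `[0, 1]` (rgb).
#' @export
combine_maps <- function(maps, kind = c("diff", "absdiff", "se", "rgb", "best"),
                         polarity = NULL) {
  kind <- match.arg(kind)
  vals <- lapply(maps, function(m) if (inherits(m, "nm_stat_map")) m$values else as.numeric(m))
  metrics <- vapply(maps, function(m) if (inherits(m, "nm_stat_map")) m$metric else NA_character_,
                    character(1))
  n <- lengths(vals)
  if (length(unique(n)) != 1) abort("maps cover different numbers of observations")
  need <- switch(kind, diff = 2L, absdiff = 2L, se = 2L, rgb = 3L, best = NA)
  if (!is.na(need) && length(vals) != need) {
    abort(sprintf("'%s' needs exactly %d maps, got %d", kind, need, length(vals)))
  }
  if (kind == "best" && length(vals) < 2) abort("'best' needs at least 2 maps")
  geometry <- maps[[1]]$geometry
  mask <- maps[[1]]$mask
  values <- switch(kind,
    diff = vals[[1]] - vals[[2]],
    absdiff = abs(vals[[1]] - vals[[2]]),
    se = (vals[[1]] - vals[[2]])^2,
    rgb = {
      ch <- vapply(vals, rescale01, numeric(n[1]))
      colnames(ch) <- c("r", "g", "b")
      ch
    },
    best = {
      if (is.null(polarity)) {
        if (anyNA(metrics) || length(unique(metrics)) != 1) {
          abort("maps carry mixed or unknown metrics; supply polarity explicitly")
        }
        polarity <- metric_polarity(metrics[1])
      }
      V <- do.call(cbind, vals)
      if (polarity == "lower") V <- -V
      max.col(V, ties.method = "first")
    })
  structure(list(kind = kind, values = values, metrics = metrics,
                 polarity = polarity, geometry = geometry, mask = mask),
            class = "nm_comparison")
}

metric_polarity <- function(metric) {
  switch(metric,
    ftest = , r2 = , significance = "higher",
    mse = , aic = , prss = , vnprss = , p_value = "lower",
    abort(sprintf("no default polarity for metric '%s'; supply one", metric)))
}

rescale01 <- function(x) {
  r <- range(x[is.finite(x)])
  if (diff(r) == 0) return(rep(0, length(x)))
  pmin(pmax((x - r[1]) / diff(r), 0), 1)
}

#' @export
print.nm_comparison <- function(x, ...) {
  cat(sprintf("<nm_comparison> kind=%s over %d observations\n",
              x$kind, NROW(x$values)))
  invisible(x)
}

#' Derivative-weighted curve distance
#'
#' Similarity between two curves on a shared uniform grid, defined as a
#' weighted sum of Euclidean distances between their discrete derivatives:
#' `SD(x, y) = sum_n w_n d_n(x, y)` for derivative orders
#' `n = 0, ..., N_D - 1`, with the default `N_D = 3` and weights
#' `(0.2, 0.8, 0.2)` emphasizing the first derivative (the shape of
#' change). The order-`n` discrete derivative is the n-fold unit-step
#' difference of the sampled curve (not divided by the grid spacing:
#' rescaling by `step^-n` would amplify any unsmoothed pointwise
#' perturbation by `1/h^n` and drown the curve shape on dense grids).
#' Because differencing shortens the curves, each `d_n` is by default
#' normalized by `sqrt(T - n)` so the orders contribute on a common
#' per-point scale; set `normalize = FALSE` for raw Euclidean norms.
#'
#' @param x,y Numeric curves of equal length `T` on the same grid.
#' @param weights Nonnegative weights, one per derivative order.
#' @param normalize Normalize each order by `sqrt(T - n)`?
#' @return Nonnegative scalar; a pseudometric over curves.
#' @export
curve_similarity <- function(x, y, weights = c(0.2, 0.8, 0.2),
                             normalize = TRUE) {
  T <- length(x)
  nd <- length(weights)
  if (length(y) != T) abort("curves must share the grid")
  if (T < nd) abort(sprintf("need at least %d grid points for %d derivative orders", nd, nd))
  if (any(weights < 0)) abort("weights must be nonnegative")
  sd_val <- 0
  for (n in seq_len(nd) - 1L) {
    dx <- if (n == 0) x else diff(x, differences = n)
    dy <- if (n == 0) y else diff(y, differences = n)
    d <- sqrt(sum((dx - dy)^2))
    if (normalize) d <- d / sqrt(T - n)
    sd_val <- sd_val + weights[n + 1] * d
  }
  sd_val
}

# Full pairwise SD matrix for an N x T curve matrix.
sd_distance_matrix <- function(curves, weights = c(0.2, 0.8, 0.2),
                               normalize = TRUE) {
  T <- ncol(curves)
  nd <- length(weights)
  if (T < nd) abort("not enough grid points for the requested derivative orders")
  D <- matrix(0, nrow(curves), nrow(curves))
  for (n in seq_len(nd) - 1L) {
    dn <- if (n == 0) curves else
      t(apply(curves, 1, function(r) diff(r, differences = n)))
    dmat <- as.matrix(dist(dn))
    if (normalize) dmat <- dmat / sqrt(T - n)
    D <- D + weights[n + 1] * dmat
  }
  D
}

#' Hierarchical clustering of fitted curves
#'
#' Agglomerative (bottom-up) clustering under the derivative-weighted
#' distance of [curve_similarity()]: every curve starts as its own cluster
#' and the pair minimizing the average linkage — the mean distance over all
#' cross-pairs of the two clusters — is merged until `n_clusters` remain.
#' Ties are broken toward the pair with the smallest original curve
#' indices. By default curves are z-scored over the grid first, so clusters
#' capture curve shape rather than amplitude.
#'
#' @param curves An `nm_curves` object or an N x T matrix of curves on a
#'   shared grid.
#' @param n_clusters Target number of clusters, `1 <= N_C <= N`.
#' @param weights,normalize Passed to the distance (see
#'   [curve_similarity()]).
#' @param standardize Z-score each curve over the grid before clustering?
#' @return An object of class `nm_cluster`: `labels` (1-based, ordered by
#'   smallest member index), `merges` (tibble of the merge history),
#'   `centroids` (pointwise mean curves on the original scale),
#'   `silhouette_mean`, `within_var`, `between_var`.
#' @export
cluster_curves <- function(curves, n_clusters, weights = c(0.2, 0.8, 0.2),
                           normalize = TRUE, standardize = TRUE) {
  mat <- curve_matrix(curves)
  N <- nrow(mat)
  if (n_clusters < 1 || n_clusters > N) {
    abort(sprintf("n_clusters must be in [1, %d]", N))
  }
  rep_mat <- if (standardize) standardize_curves(mat) else mat
  D <- sd_distance_matrix(rep_mat, weights, normalize)

  members <- as.list(seq_len(N))
  sizes <- rep(1L, N)
  ids <- seq_len(N)            # cluster id = smallest original member index
  link <- D
  diag(link) <- Inf
  active <- rep(TRUE, N)
  merges <- list()
  n_active <- N
  while (n_active > n_clusters) {
    sub <- which(active)
    lv <- link[sub, sub, drop = FALSE]
    mval <- min(lv)
    cand <- which(lv <= mval + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # smallest (id_a, id_b) pair among ties
    pa <- ids[sub[cand[, 1]]]; pb <- ids[sub[cand[, 2]]]
    lo <- pmin(pa, pb); hi <- pmax(pa, pb)
    pick <- order(lo, hi)[1]
    i <- sub[cand[pick, 1]]; j <- sub[cand[pick, 2]]
    merges[[length(merges) + 1]] <- c(a = min(ids[i], ids[j]),
                                      b = max(ids[i], ids[j]),
                                      height = mval)
    # Lance-Williams update for average linkage
    others <- setdiff(which(active), c(i, j))
    if (length(others)) {
      newl <- (sizes[i] * link[i, others] + sizes[j] * link[j, others]) /
        (sizes[i] + sizes[j])
      link[i, others] <- newl
      link[others, i] <- newl
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    ids[i] <- min(ids[i], ids[j])
    active[j] <- FALSE
    link[j, ] <- Inf; link[, j] <- Inf
    n_active <- n_active - 1L
  }
  cl <- which(active)
  cl <- cl[order(ids[cl])]
  labels <- integer(N)
  for (k in seq_along(cl)) labels[members[[cl[k]]]] <- k
  centroids <- t(vapply(seq_along(cl), function(k) {
    colMeans(mat[members[[cl[k]]], , drop = FALSE])
  }, numeric(ncol(mat))))
  diag_vals <- if (n_clusters >= 2) {
    cluster_diagnostics(mat, labels, weights,
                        normalize = normalize, standardize = standardize)
  } else list(silhouette_mean = NA_real_, within_var = NA_real_, between_var = NA_real_)
  structure(list(
    labels = labels,
    merges = if (length(merges)) as_tibble(do.call(rbind, merges)) else
      tibble(a = integer(), b = integer(), height = numeric()),
    centroids = centroids,
    silhouette_mean = diag_vals$silhouette_mean,
    within_var = diag_vals$within_var, between_var = diag_vals$between_var,
    n_clusters = n_clusters, weights = weights,
    standardize = standardize, grid = curve_grid(curves)
  ), class = "nm_cluster")
}

curve_matrix <- function(curves) {
  if (inherits(curves, "nm_curves")) curves$curves else as.matrix(curves)
}
curve_grid <- function(curves) {
  if (inherits(curves, "nm_curves")) curves$grid else NULL
}

standardize_curves <- function(mat) {
  t(apply(mat, 1, function(r) {
    s <- sd(r)
    if (s == 0) r - mean(r) else (r - mean(r)) / s
  }))
}

#' Cluster quality diagnostics
#'
#' Silhouette coefficient, within-cluster and between-cluster dispersion
#' under the derivative-weighted curve distance. The silhouette of curve i
#' is `(b - a) / max(a, b)` with `a` the mean distance to its own cluster
#' and `b` the smallest mean distance to another cluster; singletons
#' contribute 0 by convention. `within_var` is the mean distance of each
#' curve to its cluster centroid; `between_var` the mean pairwise distance
#' between centroids. Use these across a range of cluster counts to pick a
#' working number of clusters.
#'
#' @inheritParams cluster_curves
#' @param labels Integer cluster labels (>= 2 non-empty clusters).
#' @return A list: `silhouette_mean`, `silhouettes`, `within_var`,
#'   `between_var`.
#' @export
cluster_diagnostics <- function(curves, labels, weights = c(0.2, 0.8, 0.2),
                                normalize = TRUE, standardize = TRUE) {
  mat <- curve_matrix(curves)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(mat))
  ks <- sort(unique(labels))
  if (length(ks) < 2) abort("diagnostics need at least 2 clusters")
  rep_mat <- if (standardize) standardize_curves(mat) else mat
  D <- sd_distance_matrix(rep_mat, weights, normalize)
  N <- nrow(mat)
  sil <- numeric(N)
  for (i in seq_len(N)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { sil[i] <- 0; next }
    a <- mean(D[i, own & seq_len(N) != i])
    b <- min(vapply(ks[ks != labels[i]], function(k) mean(D[i, labels == k]),
                    numeric(1)))
    sil[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  centroids <- t(vapply(ks, function(k) colMeans(rep_mat[labels == k, , drop = FALSE]),
                        numeric(ncol(rep_mat))))
  within <- mean(vapply(seq_len(N), function(i) {
    curve_similarity(rep_mat[i, ], centroids[match(labels[i], ks), ],
                     weights, normalize)
  }, numeric(1)))
  cd <- sd_distance_matrix(centroids, weights, normalize)
  between <- mean(cd[upper.tri(cd)])
  list(silhouette_mean = mean(sil), silhouettes = sil,
       within_var = within, between_var = between)
}

#' @export
print.nm_cluster <- function(x, ...) {
  cat(sprintf("<nm_cluster> %d clusters over %d curves; mean silhouette %.3f\n",
              x$n_clusters, length(x$labels), x$silhouette_mean))
  invisible(x)
}

#' @export
tidy.nm_cluster <- function(x, ...) {
  tibble(id = seq_along(x$labels), cluster = x$labels)
}

#' @export
glance.nm_cluster <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, n_curves = length(x$labels),
         silhouette_mean = x$silhouette_mean,
         within_var = x$within_var, between_var = x$between_var)
}

#' @export
autoplot.nm_cluster <- function(object, ...) {
  grid <- object$grid %||% seq_len(ncol(object$centroids))
  d <- tibble(
    cluster = factor(rep(seq_len(nrow(object$centroids)), each = length(grid))),
    grid = rep(grid, nrow(object$centroids)),
    value = as.vector(t(object$centroids))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$grid, .data$value, colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "predictor", y = "centroid curve") +
    ggplot2::theme_minimal()
}
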