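#' Read a covariate table
#'
#' Loads a subjects-by-covariates table from CSV or Excel. Every retained
#' column must be numeric: categorical covariates (sex, genotype dose, ...)
#' are expected pre-encoded as numeric or dummy columns. An optional
#' non-numeric first column is treated as a subject identifier and kept as
#' an attribute so callers can cross-check it against image file order.
#'
#' @param path Path to a `.csv`, `.xls` or `.xlsx` file with a header row.
#' @param id_column Name or index of a subject-id column to set aside, or
#'   `NULL` (default) to auto-detect a non-numeric first column.
#' @return A tibble of numeric covariates with attribute `"subject_id"`
#'   (character vector or `NULL`).
#' @export
read_covariates <- function(path, id_column = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = read.csv(path, check.names = FALSE),
    xls = ,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading Excel covariates requires the 'readxl' package")
      }
      as.data.frame(readxl::read_excel(path))
    },
    abort(sprintf("unsupported covariate file extension '%s'", ext))
  )
  ids <- NULL
  if (is.null(id_column) && ncol(df) > 0 && !is.numeric(df[[1]])) id_column <- 1L
  if (!is.null(id_column)) {
    ids <- as.character(df[[id_column]])
    df <- df[, setdiff(seq_along(df), match_column(df, id_column)), drop = FALSE]
  }
  tab <- as_covariate_table(df)
  attr(tab, "subject_id") <- ids
  tab
}

match_column <- function(df, col) {
  if (is.character(col)) match(col, names(df)) else as.integer(col)
}

#' Validate a covariate table
#'
#' Checks the invariants every downstream step relies on: at least two
#' subjects, unique column names, all-numeric columns, no missing values.
#'
#' @param data A data frame of covariates (subjects in rows).
#' @return A tibble (invisibly validated).
#' @export
as_covariate_table <- function(data) {
  if (!is.data.frame(data)) data <- as.data.frame(data)
  if (nrow(data) < 2) abort("covariate table needs at least 2 subjects")
  if (anyDuplicated(names(data))) abort("covariate names must be unique")
  bad <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf(
      "non-numeric covariate column(s): %s (encode categories as numeric/dummy columns)",
      paste(bad, collapse = ", ")))
  }
  if (anyNA(data)) abort("covariate table contains missing values")
  as_tibble(data)
}

covariate_matrix <- function(data) {
  data <- as_covariate_table(data)
  m <- as.matrix(data)
  dimnames(m) <- list(NULL, names(data))
  m
}

#' Preprocess covariates
#'
#' Optional preconditioning of the covariate columns before design
#' splitting. `"normalize"` scales each column to unit Euclidean norm.
#' `"orthogonalize"` residualizes each column, in file order, on the
#' implicit intercept and on all earlier columns (sequential Gram-Schmidt
#' without rescaling), so confounders placed first absorb shared variance;
#' because the intercept participates, all output columns are mean-centered.
#' `"orthonormalize"` orthogonalizes and then normalizes.
#'
#' @param data Covariate table (data frame, subjects in rows).
#' @param mode One of `"normalize"`, `"orthogonalize"`, `"orthonormalize"`.
#' @param tol Relative tolerance below which a residualized column is
#'   declared linearly dependent on its predecessors.
#' @return A tibble with the same shape and names as `data`.
#' @export
preprocess_covariates <- function(data,
                                  mode = c("normalize", "orthogonalize", "orthonormalize"),
                                  tol = 1e-10) {
  mode <- match.arg(mode)
  X <- covariate_matrix(data)
  if (mode == "normalize") {
    nrm <- sqrt(colSums(X^2))
    zero <- nrm <= 0
    if (any(zero)) {
      abort(sprintf("cannot normalize zero-norm covariate(s): %s",
                    paste(colnames(X)[zero], collapse = ", ")))
    }
    out <- sweep(X, 2, nrm, "/")
    return(as_tibble(as.data.frame(out)))
  }
  # Gram-Schmidt in column order; the intercept is column zero, so every
  # output column is centered.  Scales are kept (no renormalization here).
  L <- nrow(X)
  Q <- matrix(0, L, 0)
  out <- X
  for (j in seq_len(ncol(X))) {
    v <- X[, j] - mean(X[, j])
    if (ncol(Q) > 0) v <- v - Q %*% crossprod(Q, v)
    scale_ref <- sqrt(sum((X[, j] - mean(X[, j]))^2))
    if (sqrt(sum(v^2)) <= tol * max(scale_ref, 1)) {
      abort(sprintf(
        "covariate '%s' is linearly dependent on earlier columns; cannot orthogonalize",
        colnames(X)[j]))
    }
    out[, j] <- v
    Q <- cbind(Q, v / sqrt(sum(v^2)))
  }
  if (mode == "orthonormalize") {
    out <- sweep(out, 2, sqrt(colSums(out^2)), "/")
  }
  as_tibble(as.data.frame(out))
}

#' Build a contrast specification
#'
#' A contrast matrix `C` (M covariates x P predictor directions) defines the
#' predictor subspace of the design; the complementary corrector subspace is
#' obtained through the null-contrast projector `C0 = I - C C^+`, with `C^+`
#' the Moore-Penrose pseudoinverse of `C`. `C0` annihilates `C`
#' (`C0 C = 0`) and is idempotent; both identities are verified at build
#' time.
#'
#' @param C Numeric matrix with one row per covariate and `1 <= P < M`
#'   columns (a vector is taken as a single-column contrast).
#' @param tol Relative tolerance for the pseudoinverse (singular values below
#'   `tol * max(singular value)` are treated as zero) and for the projector
#'   identity checks.
#' @return An object of class `nm_contrast` with elements `C`, `C0`,
#'   `pinv` and `tol`.
#' @export
build_contrast <- function(C, tol = 1e-8) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  M <- nrow(C); P <- ncol(C)
  if (P < 1 || P >= M) abort("contrast must have 1 <= P < M columns")
  if (all(C == 0)) abort("contrast matrix is all zero")
  pinv <- pseudoinverse(C, tol)
  C0 <- diag(M) - C %*% pinv
  scale <- max(abs(C0), 1)
  if (max(abs(C0 %*% C)) > tol * 1e2 * scale * max(abs(C))) {
    abort("null-contrast does not annihilate the contrast; C may be ill-conditioned")
  }
  if (max(abs(C0 %*% C0 - C0)) > tol * 1e2 * scale) {
    abort("null-contrast projector is not idempotent at the given tolerance")
  }
  structure(list(C = C, C0 = C0, pinv = pinv, tol = tol), class = "nm_contrast")
}

# Moore-Penrose pseudoinverse by SVD with a relative singular-value cutoff.
pseudoinverse <- function(A, tol = 1e-8) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) abort("matrix has no singular values above tolerance")
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Split the design into corrector and predictor subspaces
#'
#' Projects the covariate matrix `X` onto the predictor subspace
#' (`XP = X C`) and the corrector subspace (`XC = X C0`). Corrector columns
#' that the projection sends to zero are dropped, with the kept indices
#' recorded. The two subspaces are orthogonal only when the columns of `X`
#' are orthogonal.
#'
#' @param data Covariate table (data frame, subjects in rows).
#' @param contrast An `nm_contrast` from [build_contrast()], whose row count
#'   must equal the number of covariates.
#' @param zero_tol Columns of `XC` with Euclidean norm at or below
#'   `zero_tol` times the largest column norm of `X` are dropped.
#' @return An object of class `nm_design`: `XC`, `XP`, `kept_correctors`
#'   (indices into the original covariates), `df_C`, `df_P`, `L`,
#'   `names`, and the `contrast` used.
#' @export
split_design <- function(data, contrast, zero_tol = 1e-10) {
  stopifnot(inherits(contrast, "nm_contrast"))
  X <- covariate_matrix(data)
  if (ncol(X) != nrow(contrast$C)) {
    abort(sprintf("contrast has %d rows but the table has %d covariates",
                  nrow(contrast$C), ncol(X)))
  }
  XP <- X %*% contrast$C
  XC <- X %*% contrast$C0
  ref <- max(sqrt(colSums(X^2)), 1)
  keep <- sqrt(colSums(XC^2)) > zero_tol * ref
  XC <- XC[, keep, drop = FALSE]
  colnames(XC) <- colnames(X)[keep]
  colnames(XP) <- paste0("pred", seq_len(ncol(XP)))
  structure(list(
    XC = XC, XP = XP,
    kept_correctors = which(keep),
    df_C = ncol(XC), df_P = ncol(XP),
    L = nrow(X), names = colnames(X),
    contrast = contrast
  ), class = "nm_design")
}

#' @export
print.nm_design <- function(x, ...) {
  cat(sprintf("<nm_design> L=%d subjects, %d corrector column(s), %d predictor column(s)\n",
              x$L, ncol(x$XC), ncol(x$XP)))
  invisible(x)
}

#' Build a design split directly from named covariate roles
#'
#' Convenience wrapper: a contrast selecting the named predictor columns is
#' constructed (unit columns), all remaining covariates becoming correctors.
#'
#' @param data Covariate table.
#' @param predictors Character vector of predictor column names.
#' @inheritParams split_design
#' @return An `nm_design`.
#' @export
split_by_role <- function(data, predictors, zero_tol = 1e-10) {
  data <- as_covariate_table(data)
  idx <- match(predictors, names(data))
  if (anyNA(idx)) {
    abort(sprintf("predictor(s) not found in covariates: %s",
                  paste(predictors[is.na(idx)], collapse = ", ")))
  }
  M <- ncol(data)
  C <- matrix(0, M, length(idx))
  C[cbind(idx, seq_along(idx))] <- 1
  split_design(data, build_contrast(C), zero_tol = zero_tol)
}
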