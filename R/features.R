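#' Z-score the columns of a feature table
#'
#' Standardizes each feature as `z = (x - m) / s`. With
#' `stats_source = "population"` the mean and SD of the whole table are used
#' (so every transformed column has mean 0, SD 1). With the default
#' `"train_only"` mode, statistics are taken from the rows given in `train`
#' and applied to all rows — the leakage-safe variant used inside
#' cross-validation. Zero-variance features cannot be standardized and are
#' dropped with a warning.
#'
#' @param table A [feature_table()].
#' @param stats_source `"train_only"` or `"population"`.
#' @param train Row indices supplying the statistics in `train_only` mode
#'   (default: all rows, which makes the two modes coincide).
#' @return The standardized `feature_table`, with the statistics attached as
#'   attributes `m_x` and `s_x`.
#' @export
zscore_table <- function(table, stats_source = c("train_only", "population"),
                         train = seq_len(nrow(table$x))) {
  stats_source <- match.arg(stats_source)
  rows <- if (stats_source == "population") seq_len(nrow(table$x)) else train
  m <- colMeans(table$x[rows, , drop = FALSE])
  s <- apply(table$x[rows, , drop = FALSE], 2, stats::sd)
  keep <- is.finite(s) & s > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance feature(s): ",
            paste(colnames(table$x)[!keep], collapse = ", "))
  }
  z <- sweep(sweep(table$x[, keep, drop = FALSE], 2, m[keep], `-`),
             2, s[keep], `/`)
  out <- feature_table(z, table$labels, domain = table$domain,
                       subject_id = table$subject_id)
  attr(out, "m_x") <- m[keep]
  attr(out, "s_x") <- s[keep]
  out
}

#' Fit PCA on a training matrix
#'
#' Principal components analysis on the mean-centered (not re-scaled)
#' training matrix. With `N` training subjects at most `N - 1` components
#' have nonzero variance, so the model keeps `min(N - 1, p)` components,
#' sorted by decreasing explained variance; training-set coefficients are
#' mutually uncorrelated.
#'
#' @param train_matrix Numeric matrix, training subjects x features.
#' @return An object of class `pca_model`: `loadings` (features x
#'   components, orthonormal), `center`, `sdev` (component SDs,
#'   non-increasing), `n_components`.
#' @export
fit_pca <- function(train_matrix) {
  train_matrix <- as.matrix(train_matrix)
  n <- nrow(train_matrix)
  if (n < 2) stop("PCA requires at least 2 training subjects")
  if (all(apply(train_matrix, 2, stats::sd) == 0))
    stop("constant training matrix: PCA undefined")
  k <- min(n - 1L, ncol(train_matrix))
  pr <- stats::prcomp(train_matrix, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 center = pr$center,
                 sdev = pr$sdev[seq_len(k)],
                 n_components = k),
            class = "pca_model")
}

#' Project subjects onto a fitted PCA basis
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param matrix Subjects x features matrix (same feature space as the fit).
#' @return Subjects x components coefficient matrix.
#' @export
project_pca <- function(model, matrix) {
  stopifnot(inherits(model, "pca_model"))
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != nrow(model$loadings))
    stop("feature dimension mismatch: ", ncol(matrix), " vs ",
         nrow(model$loadings))
  sweep(matrix, 2, model$center, `-`) %*% model$loadings
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model A `pca_model`.
#' @param path JSON path.
#' @return `write_pca_model()` returns `path` invisibly;
#'   `read_pca_model()` the restored model.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- as.matrix(obj$loadings)
  obj$n_components <- as.integer(obj$n_components)
  structure(obj, class = "pca_model")
}

#' Fisher discriminant ratio ranking of features
#'
#' Scores each feature (column) by its Fisher discriminant ratio,
#' `FDR = (mu_ADHD - mu_TD)^2 / (var_ADHD + var_TD)`, a univariate measure
#' of binary-class separability (not the false-discovery rate), and ranks
#' features by decreasing score. Group variances use the `n - 1`
#' denominator. Degenerate columns: when both class variances are zero the
#' score is 0 for equal means and `Inf` (ranked first) for distinct means.
#' Ties are broken by original column index (stable).
#'
#' @param coefficients Subjects x features numeric matrix (e.g. PCA
#'   coefficients or raw features).
#' @param labels ADHD/TD labels, one per row.
#' @return An object of class `fdr_ranking`: per-feature `mu_adhd`,
#'   `mu_td`, `var_adhd`, `var_td`, `fdr`, and `rank` (feature indices in
#'   decreasing score order).
#' @export
fdr_rank <- function(coefficients, labels) {
  coefficients <- as.matrix(coefficients)
  labels <- as.character(labels)
  if (!all(c("ADHD", "TD") %in% labels))
    stop("both classes must be present to rank features")
  a <- coefficients[labels == "ADHD", , drop = FALSE]
  t_ <- coefficients[labels == "TD", , drop = FALSE]
  mu_a <- colMeans(a); mu_t <- colMeans(t_)
  va <- apply(a, 2, stats::var); vt <- apply(t_, 2, stats::var)
  num <- (mu_a - mu_t)^2
  den <- va + vt
  fdr <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  structure(list(mu_adhd = mu_a, mu_td = mu_t,
                 var_adhd = va, var_td = vt, fdr = fdr,
                 rank = order(-fdr, seq_along(fdr))),
            class = "fdr_ranking")
}

#' Retain the top fraction of ranked features
#'
#' Keeps the `ceiling(fraction * n)` highest-scoring features of an FDR
#' ranking (default 60%), in rank order. The ceiling rule makes a 60%
#' retention of either 19 or 20 PCA coefficients yield exactly 12.
#'
#' @param ranking An `fdr_ranking`, or a plain ranked index vector.
#' @param fraction Fraction to retain, in (0, 1].
#' @return Integer vector of retained feature indices, highest score first.
#' @export
select_top_fraction <- function(ranking, fraction = 0.6) {
  idx <- if (inherits(ranking, "fdr_ranking")) ranking$rank else as.integer(ranking)
  if (length(idx) == 0) stop("empty ranking")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * length(idx))
  idx[seq_len(k)]
}
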