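#' Feature-engineering recipes for the classification pipeline
#'
#' Returns a function `(x, labels, train_idx, test_idx)` producing engineered
#' candidate matrices `xtr`/`xte`, with every statistic fitted on the
#' training rows only, so held-out subjects can never influence the
#' transform.
#'
#' Two recipes exist:
#' \describe{
#'   \item{`tabular`}{z-scoring by training-fold mean/SD (NPS and BIO
#'     features). A training-fold zero-variance feature is mapped to a zero
#'     column so the candidate identity is stable across splits.
#'     `stats_source = "population"` instead freezes the statistics on the
#'     full table beforehand — the variant that mirrors whole-cohort
#'     z-scoring and is provided as an explicit divergence switch.}
#'   \item{`nirs`}{mean-centering and PCA fitted on the training rows
#'     (yielding at most `N - 1` coefficients), FDR ranking of the training
#'     coefficients, and retention of the top `fraction` (default 60%),
#'     optionally capped at `max_features` to bound the exhaustive search.
#'     Candidates are identified by FDR rank position.}
#' }
#'
#' @param type `"tabular"` or `"nirs"`.
#' @param stats_source For `tabular`: `"train_only"` (default) or
#'   `"population"`.
#' @param fraction For `nirs`: fraction of ranked coefficients retained.
#' @param max_features For `nirs`: cap on the number of candidates
#'   (`NULL` = no cap).
#' @return An engineering function for [prepare_inner_splits()] and
#'   [nested_cv()].
#' @export
make_engineer <- function(type = c("tabular", "nirs"),
                          stats_source = c("train_only", "population"),
                          fraction = 0.6, max_features = NULL) {
  type <- match.arg(type)
  stats_source <- match.arg(stats_source)
  if (type == "tabular") {
    function(x, labels, train_idx, test_idx) {
      rows <- if (stats_source == "population") seq_len(nrow(x)) else train_idx
      m <- colMeans(x[rows, , drop = FALSE])
      s <- apply(x[rows, , drop = FALSE], 2, stats::sd)
      zs <- function(idx) {
        z <- sweep(x[idx, , drop = FALSE], 2, m, `-`)
        ok <- is.finite(s) & s > 0
        z[, ok] <- sweep(z[, ok, drop = FALSE], 2, s[ok], `/`)
        z[, !ok] <- 0
        z
      }
      list(xtr = zs(train_idx), xte = zs(test_idx))
    }
  } else {
    function(x, labels, train_idx, test_idx) {
      pca <- fit_pca(x[train_idx, , drop = FALSE])
      ctr <- project_pca(pca, x[train_idx, , drop = FALSE])
      cte <- project_pca(pca, x[test_idx, , drop = FALSE])
      ranking <- fdr_rank(ctr, labels[train_idx])
      keep <- select_top_fraction(ranking, fraction)
      if (!is.null(max_features)) keep <- keep[seq_len(min(length(keep), max_features))]
      nm <- paste0("pc_rank_", seq_along(keep))
      xtr <- ctr[, keep, drop = FALSE]; colnames(xtr) <- nm
      xte <- cte[, keep, drop = FALSE]; colnames(xte) <- nm
      list(xtr = xtr, xte = xte)
    }
  }
}
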