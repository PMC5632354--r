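#' Enumerate every non-empty feature subset
#'
#' Generates all `2^p - 1` non-empty subsets of `p` candidate features, in
#' the deterministic preference order used for tie-breaking throughout the
#' wrapper search: smaller subsets first, then lexicographic on the sorted
#' indices.
#'
#' @param p Number of candidate features (guarded at `p <= 25` unless
#'   `force = TRUE`; the exhaustive search is exponential in `p`).
#' @param force Override the guard.
#' @return A list with `count` (`2^p - 1`) and `subsets` (list of integer
#'   vectors in preference order).
#' @export
enumerate_subsets <- function(p, force = FALSE) {
  p <- as.integer(p)
  if (p < 1) stop("p must be >= 1")
  if (p > 25 && !force)
    stop("p = ", p, " implies ", 2^p - 1,
         " subsets; pass force = TRUE to proceed")
  subsets <- unlist(lapply(seq_len(p), function(k) {
    m <- utils::combn(p, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), recursive = FALSE)
  list(count = 2^p - 1, subsets = subsets)
}

#' Prepare the inner cross-validation splits of a wrapper search
#'
#' Given the 9 inner subject subsets of one outer round, builds for each
#' inner split (one subset held out, the rest training) the engineered
#' candidate feature matrices, refitting the full feature pipeline —
#' z-scoring, and for NIRS domains PCA, FDR ranking and top-fraction
#' retention — on the split's training subjects only. Splits whose training
#' part lacks a class are skipped with a warning. Because the candidate
#' count can differ slightly across splits (PCA yields `N - 1` components),
#' all splits are truncated to the common minimum, which becomes the
#' wrapper's search dimension `p`.
#'
#' @param table A [feature_table()] restricted to the inner pool.
#' @param inner_subsets List of index vectors (relative to `table`) forming
#'   the inner subsets.
#' @param engineer An engineering function from [make_engineer()].
#' @return A list of class `inner_pool`: `splits` (each with `xtr`, `ytr`,
#'   `xte`, `yte`) and `p` (common candidate count).
#' @export
prepare_inner_splits <- function(table, inner_subsets, engineer) {
  splits <- list()
  for (i in seq_along(inner_subsets)) {
    test_idx <- inner_subsets[[i]]
    train_idx <- setdiff(seq_len(nrow(table$x)), test_idx)
    if (length(unique(table$labels[train_idx])) < 2) {
      warning("inner split ", i, " has a single-class training set; skipped")
      next
    }
    eng <- engineer(table$x, table$labels, train_idx, test_idx)
    splits[[length(splits) + 1]] <-
      list(xtr = eng$xtr, ytr = table$labels[train_idx],
           xte = eng$xte, yte = table$labels[test_idx])
  }
  if (!length(splits)) stop("no usable inner splits")
  p <- min(vapply(splits, function(s) ncol(s$xtr), 0L))
  splits <- lapply(splits, function(s) {
    s$xtr <- s$xtr[, seq_len(p), drop = FALSE]
    s$xte <- s$xte[, seq_len(p), drop = FALSE]
    s
  })
  structure(list(splits = splits, p = p), class = "inner_pool")
}

#' Inner-loop accuracy of one feature subset
#'
#' Scores a candidate subset by cross-validation over the prepared inner
#' splits: each inner subset is held out once against the remaining ones,
#' and the score is the pooled accuracy of the held-out predictions.
#'
#' @param subset Integer vector of candidate feature indices (non-empty).
#' @param pool An `inner_pool` from [prepare_inner_splits()].
#' @return Pooled accuracy fraction in `[0, 1]`.
#' @export
inner_score <- function(subset, pool) {
  stopifnot(inherits(pool, "inner_pool"), length(subset) >= 1)
  correct <- 0L; total <- 0L
  for (s in pool$splits) {
    model <- train_svm(s$xtr[, subset, drop = FALSE], s$ytr)
    pred <- predict(model, s$xte[, subset, drop = FALSE])
    correct <- correct + sum(pred == s$yte)
    total <- total + length(s$yte)
  }
  correct / total
}

#' Exhaustive wrapper optimization of the feature subset
#'
#' Evaluates every non-empty subset of the `p` candidate features through
#' [inner_score()] and returns the one with the highest inner accuracy.
#' Ties are broken deterministically toward smaller subsets, then
#' lexicographically on sorted indices.
#'
#' @param pool An `inner_pool` from [prepare_inner_splits()].
#' @param force Passed to [enumerate_subsets()].
#' @return A list of class `subset_search`: `evaluated_count`
#'   (`2^p - 1`), `best_subset`, `best_inner_score`.
#' @export
optimize_subset <- function(pool, force = FALSE) {
  stopifnot(inherits(pool, "inner_pool"))
  enum <- enumerate_subsets(pool$p, force = force)
  best <- NULL; best_score <- -Inf
  for (subset in enum$subsets) {
    sc <- inner_score(subset, pool)
    if (sc > best_score) {       # strict: earlier (preferred) subset wins ties
      best <- subset
      best_score <- sc
    }
  }
  structure(list(evaluated_count = enum$count, best_subset = best,
                 best_inner_score = best_score),
            class = "subset_search")
}
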