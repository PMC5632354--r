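#' Seeded stratified fold plan
#'
#' Partitions the subjects into `k` pairwise-disjoint subsets of sizes
#' differing by at most one, stratified by label: within each class the
#' subjects are shuffled, the classes are concatenated, and fold labels
#' `1..k` are dealt sequentially along that ordering. If the plan would
#' leave any outer training set single-class (only possible for tiny
#' classes), it is re-drawn with a derived seed.
#'
#' @param labels ADHD/TD labels, one per subject.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `folds` (list of
#'   index vectors), `k`, `seed`, `n`.
#' @export
make_fold_plan <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < k) stop("need at least k subjects for a ", k, "-fold plan")
  for (attempt in 0:20) {
    set.seed(seed + attempt * 7919L)
    ord <- c(sample(which(labels == "ADHD")), sample(which(labels == "TD")))
    assign <- rep_len(seq_len(k), n)
    folds <- lapply(seq_len(k), function(f) sort(ord[assign == f]))
    ok <- all(vapply(seq_len(k), function(f) {
      train <- unlist(folds[-f])
      length(unique(labels[train])) == 2
    }, TRUE))
    if (ok)
      return(structure(list(folds = folds, k = k, seed = seed, n = n),
                       class = "fold_plan"))
  }
  stop("could not build a fold plan with both classes in every training set")
}

#' Classification metrics on one fold
#'
#' ADHD is the positive class: sensitivity is the ADHD true-positive rate,
#' specificity the TD true-negative rate. A fold lacking positives
#' (negatives) yields `NA` sensitivity (specificity), excluded from
#' cross-fold means.
#'
#' @param predicted,actual Label vectors.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
fold_metrics <- function(predicted, actual) {
  predicted <- as.character(predicted); actual <- as.character(actual)
  if (!length(actual)) stop("empty fold")
  pos <- actual == "ADHD"
  c(accuracy = mean(predicted == actual),
    sensitivity = if (any(pos)) mean(predicted[pos] == "ADHD") else NA_real_,
    specificity = if (any(!pos)) mean(predicted[!pos] == "TD") else NA_real_)
}

#' Nested cross-validation with exhaustive wrapper feature selection
#'
#' The full evaluation protocol: the cohort is split into `k` subsets (the
#' fold plan). In each of the `k` rounds one subset is held out; the other
#' `k - 1` form the inner pool, on which the optimal feature subset is found
#' by exhaustive wrapper search ([optimize_subset()]) with inner
#' cross-validation. One linear SVM is then trained on the whole inner pool
#' using the optimal subset (feature engineering refitted on the pool) and
#' evaluated on the held-out subset. Accuracy, sensitivity and specificity
#' are computed per round and averaged across rounds; every subject is
#' predicted exactly once.
#'
#' @param table A [feature_table()] for one domain.
#' @param plan A [make_fold_plan()] (its `n` must match the table).
#' @param engineer Engineering recipe from [make_engineer()]; defaults to
#'   the tabular recipe for NPS/BIO tables and the PCA/FDR recipe for NIRS
#'   tables.
#' @param force Passed to [enumerate_subsets()].
#' @param verbose Print one progress line per round (evaluated-combination
#'   counts included).
#' @return An object of class `nested_cv_result`: `rounds` (per-round list
#'   with `best_subset`, `best_inner_score`, `evaluated_count`, `metrics`),
#'   `metrics` (k x 3 matrix), `mean`, `sd`, `predictions` (data.frame
#'   subject/fold/actual/predicted/margin in subject order), `plan`,
#'   `domain`, `candidate_names`.
#' @export
nested_cv <- function(table, plan,
                      engineer = NULL,
                      force = FALSE, verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "fold_plan"))
  if (plan$n != nrow(table$x))
    stop("fold plan covers ", plan$n, " subjects but table has ", nrow(table$x))
  if (is.null(engineer)) {
    engineer <- if (table$domain %in% c("NPS", "BIO"))
      make_engineer("tabular") else make_engineer("nirs")
  }
  n <- nrow(table$x)
  pred <- rep(NA_character_, n)
  marg <- rep(NA_real_, n)
  fold_of <- rep(NA_integer_, n)
  rounds <- vector("list", plan$k)
  metrics <- matrix(NA_real_, plan$k, 3,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity")))
  candidate_names <- NULL

  for (r in seq_len(plan$k)) {
    test_idx <- plan$folds[[r]]
    pool_idx <- sort(unlist(plan$folds[-r]))
    if (length(unique(table$labels[pool_idx])) < 2)
      stop("outer training set of round ", r, " is single-class; re-plan")
    pool_tab <- subset_subjects(table, pool_idx)
    # inner subsets re-indexed relative to the pool
    inner_subsets <- lapply(plan$folds[-r],
                            function(f) match(f, pool_idx))
    pool <- prepare_inner_splits(pool_tab, inner_subsets, engineer)
    search <- optimize_subset(pool, force = force)

    eng <- engineer(table$x, table$labels, pool_idx, test_idx)
    p_final <- min(ncol(eng$xtr), pool$p)
    subset <- search$best_subset[search$best_subset <= p_final]
    if (!length(subset)) subset <- seq_len(p_final)
    model <- train_svm(eng$xtr[, subset, drop = FALSE],
                       table$labels[pool_idx])
    out <- predict(model, eng$xte[, subset, drop = FALSE])
    pred[test_idx] <- out
    marg[test_idx] <- attr(out, "margin")
    fold_of[test_idx] <- r
    metrics[r, ] <- fold_metrics(out, table$labels[test_idx])
    if (is.null(candidate_names))
      candidate_names <- colnames(eng$xtr)[seq_len(pool$p)]
    rounds[[r]] <- list(best_subset = search$best_subset,
                        best_inner_score = search$best_inner_score,
                        evaluated_count = search$evaluated_count,
                        metrics = metrics[r, ])
    if (verbose)
      message(sprintf(
        "[%s] round %d/%d: %d combinations evaluated, inner acc %.3f, outer acc %.3f",
        table$domain, r, plan$k, search$evaluated_count,
        search$best_inner_score, metrics[r, "accuracy"]))
  }
  if (is.null(candidate_names))
    candidate_names <- paste0("c", seq_len(max(unlist(
      lapply(rounds, `[[`, "best_subset")))))
  structure(list(
    rounds = rounds,
    metrics = metrics,
    mean = colMeans(metrics, na.rm = TRUE),
    sd = apply(metrics, 2, stats::sd, na.rm = TRUE),
    predictions = data.frame(subject_id = table$subject_id,
                             fold = fold_of,
                             actual = table$labels,
                             predicted = pred,
                             margin = marg,
                             stringsAsFactors = FALSE),
    plan = plan, domain = table$domain,
    candidate_names = candidate_names),
    class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result>", x$domain, "-", x$plan$k, "rounds\n")
  cat(sprintf("  accuracy    %5.1f +/- %4.1f %%\n",
              100 * x$mean["accuracy"], 100 * x$sd["accuracy"]))
  cat(sprintf("  sensitivity %5.1f +/- %4.1f %%\n",
              100 * x$mean["sensitivity"], 100 * x$sd["sensitivity"]))
  cat(sprintf("  specificity %5.1f +/- %4.1f %%\n",
              100 * x$mean["specificity"], 100 * x$sd["specificity"]))
  invisible(x)
}

#' Occurrence-frequency feature importance
#'
#' A feature's importance is the number of rounds (0..k) in which it
#' appears in the round-optimal subset; features never selected are
#' reported with count 0.
#'
#' @param result A `nested_cv_result`.
#' @return A data.frame of class `importance_profile` with columns
#'   `feature` and `count`, in decreasing count order (ties by candidate
#'   index).
#' @export
importance <- function(result) {
  stopifnot(inherits(result, "nested_cv_result"))
  p <- length(result$candidate_names)
  counts <- integer(p)
  for (r in result$rounds) {
    sel <- r$best_subset[r$best_subset <= p]
    counts[sel] <- counts[sel] + 1L
  }
  ord <- order(-counts, seq_len(p))
  out <- data.frame(feature = result$candidate_names[ord],
                    count = counts[ord], stringsAsFactors = FALSE)
  class(out) <- c("importance_profile", "data.frame")
  out
}
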