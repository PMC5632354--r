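#' Majority vote over member-model predictions
#'
#' Each member model casts one label vote per subject; the ensemble label
#' is the class with most votes. A 2-2 split in a four-member ensemble is
#' resolved by the sum of the members' signed decision margins (positive =
#' ADHD side); without margins, ties go to TD.
#'
#' @param votes Subjects x members character matrix of `"ADHD"`/`"TD"`
#'   votes (at least 3 members).
#' @param margins Optional subjects x members numeric matrix of signed
#'   decision values aligned with `votes`.
#' @return Character vector of ensemble labels, with the per-subject ADHD
#'   vote count attached as attribute `"score"`.
#' @export
majority_vote <- function(votes, margins = NULL) {
  votes <- as.matrix(votes)
  if (ncol(votes) < 3) stop("majority vote requires at least 3 members")
  if (!all(votes %in% c("ADHD", "TD"))) stop("votes must be 'ADHD' or 'TD'")
  if (!is.null(margins)) {
    margins <- as.matrix(margins)
    stopifnot(all(dim(margins) == dim(votes)))
  }
  n_adhd <- rowSums(votes == "ADHD")
  n_td <- ncol(votes) - n_adhd
  out <- ifelse(n_adhd > n_td, "ADHD",
                ifelse(n_adhd < n_td, "TD", NA))
  tied <- is.na(out)
  if (any(tied)) {
    if (!is.null(margins)) {
      out[tied] <- ifelse(rowSums(margins)[tied] > 0, "ADHD", "TD")
    } else {
      out[tied] <- "TD"
    }
  }
  attr(out, "score") <- n_adhd
  out
}

#' AUC of a discrete vote-count score
#'
#' Rank-based (Wilcoxon) integration of the ROC curve of the per-subject
#' ADHD vote count against the true labels; ties contribute 1/2.
#'
#' @param score Numeric score (larger = more ADHD-like).
#' @param labels True ADHD/TD labels.
#' @return AUC in `[0, 1]`.
#' @export
vote_auc <- function(score, labels) {
  labels <- as.character(labels)
  pos <- labels == "ADHD"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The standard suite of classifier ensembles
#'
#' @return The five member combinations of domain tags the pipeline
#'   evaluates by default: the four three-member combinations and the full
#'   four-member one.
#' @export
standard_combos <- function() {
  list(c("NPS", "BIO", "NIRS_OXY"),
       c("NPS", "BIO", "NIRS_DEOXY"),
       c("NPS", "NIRS_OXY", "NIRS_DEOXY"),
       c("BIO", "NIRS_OXY", "NIRS_DEOXY"),
       c("NPS", "BIO", "NIRS_OXY", "NIRS_DEOXY"))
}

#' Score majority-vote ensembles of domain-specific models
#'
#' Combines the pooled outer-fold predictions of domain-specific nested-CV
#' results (which must share one fold plan, so each subject is voted on
#' exactly once per member) by [majority_vote()], and scores each requested
#' member combination: fold-wise accuracy/sensitivity/specificity
#' (mean +/- SD across the shared outer folds) and the AUC of the
#' vote-count score.
#'
#' @param domain_results Named list of `nested_cv_result`s; names are
#'   domain tags (`NPS`, `BIO`, `NIRS_OXY`, `NIRS_DEOXY`).
#' @param combos List of member-tag vectors (default [standard_combos()],
#'   restricted to available domains).
#' @return An object of class `ensemble_result`: data.frame with one row
#'   per combo (`members`, `accuracy`, `accuracy_sd`, `sensitivity`,
#'   `sensitivity_sd`, `specificity`, `specificity_sd`, `auc`), with the
#'   per-combo label vectors attached as attribute `"labels"`.
#' @export
ensemble_suite <- function(domain_results, combos = standard_combos()) {
  stopifnot(length(domain_results) >= 3)
  tags <- names(domain_results)
  ref <- domain_results[[1]]
  for (d in domain_results) {
    stopifnot(inherits(d, "nested_cv_result"))
    if (!identical(d$plan$folds, ref$plan$folds))
      stop("all domain results must share one fold plan")
    if (!identical(d$predictions$actual, ref$predictions$actual))
      stop("domain results disagree on the true labels")
  }
  combos <- Filter(function(cm) all(cm %in% tags), combos)
  if (!length(combos)) stop("no combo is covered by the supplied domains")

  actual <- ref$predictions$actual
  plan <- ref$plan
  rows <- list(); all_labels <- list()
  for (cm in combos) {
    votes <- sapply(domain_results[cm], function(d) d$predictions$predicted)
    margins <- sapply(domain_results[cm], function(d) d$predictions$margin)
    final <- majority_vote(votes, margins)
    score <- attr(final, "score")
    per_fold <- t(sapply(seq_len(plan$k), function(f) {
      idx <- plan$folds[[f]]
      fold_metrics(final[idx], actual[idx])
    }))
    key <- paste(cm, collapse = "+")
    rows[[key]] <- data.frame(
      members = key,
      accuracy = mean(per_fold[, "accuracy"], na.rm = TRUE),
      accuracy_sd = stats::sd(per_fold[, "accuracy"], na.rm = TRUE),
      sensitivity = mean(per_fold[, "sensitivity"], na.rm = TRUE),
      sensitivity_sd = stats::sd(per_fold[, "sensitivity"], na.rm = TRUE),
      specificity = mean(per_fold[, "specificity"], na.rm = TRUE),
      specificity_sd = stats::sd(per_fold[, "specificity"], na.rm = TRUE),
      auc = vote_auc(score, actual),
      stringsAsFactors = FALSE)
    all_labels[[key]] <- as.character(final)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "labels") <- all_labels
  class(out) <- c("ensemble_result", "data.frame")
  out
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> majority-vote ensembles (metrics in %):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-35s acc %5.1f +/- %4.1f  sens %5.1f +/- %4.1f  spec %5.1f +/- %4.1f  AUC %.2f\n",
                x$members[i],
                100 * x$accuracy[i], 100 * x$accuracy_sd[i],
                100 * x$sensitivity[i], 100 * x$sensitivity_sd[i],
                100 * x$specificity[i], 100 * x$specificity_sd[i],
                x$auc[i]))
  }
  invisible(x)
}
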