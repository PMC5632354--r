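#' Pearson chi-square on a 2x2 contingency table
#'
#' The uncorrected Pearson statistic (no Yates continuity correction), as
#' used to compare categorical demographics (e.g. gender distribution)
#' between groups.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A list with `statistic`, `df`, `p_value`. The p-value is the
#'   asymptotic chi-square tail probability; with small expected counts it
#'   is approximate.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Compares a continuous demographic (age, IQ, socioeconomic status)
#' between the two groups with the classic equal-variance t test.
#'
#' @param x,y Numeric samples for the two groups (each of length >= 2).
#' @return A list with `statistic`, `df`, `p_value`, and the group
#'   `mean_x`, `mean_y`.
#' @export
group_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}
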