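#' Run the full multi-domain classification on a cohort
#'
#' Preprocesses the cohort's fNIRS recordings into OXY and DEOXY feature
#' tables, builds one shared stratified fold plan, and runs the nested-CV
#' wrapper classification independently on each requested domain. The
#' shared plan makes the per-domain outer predictions directly ensemblable
#' with [ensemble_suite()].
#'
#' @param cohort A [simulate_cohort()] cohort (or a compatible list with
#'   `nps`, `bio`, `nirs`, `labels` elements).
#' @param domains Domain tags to classify (subset of `NPS`, `BIO`,
#'   `NIRS_OXY`, `NIRS_DEOXY`).
#' @param k Outer fold count (default 10).
#' @param seed Seed for the fold plan.
#' @param max_features Candidate-count cap for the NIRS wrapper search
#'   (the exhaustive search is exponential; `NULL` = full top-60%
#'   retention).
#' @param max_tabular_features Optional cap applied to NPS/BIO tables by
#'   truncation to the first columns (runtime guard for small runs;
#'   `NULL` = all features).
#' @param downsample Downsampling factor for the fNIRS feature vectors.
#' @param verbose Print per-round progress.
#' @return A named list of `nested_cv_result`s, one per domain, sharing one
#'   fold plan.
#' @export
classify_cohort <- function(cohort,
                            domains = c("NPS", "BIO", "NIRS_OXY", "NIRS_DEOXY"),
                            k = 10L, seed = 1L,
                            max_features = 10L,
                            max_tabular_features = NULL,
                            downsample = 10L, verbose = FALSE) {
  domains <- match.arg(domains, several.ok = TRUE)
  plan <- make_fold_plan(cohort$labels, k = k, seed = seed)
  tables <- list()
  if ("NPS" %in% domains) tables$NPS <- cohort$nps
  if ("BIO" %in% domains) tables$BIO <- cohort$bio
  if ("NIRS_OXY" %in% domains)
    tables$NIRS_OXY <- nirs_feature_table(cohort$nirs$OXY, cohort$labels,
                                          downsample = downsample)
  if ("NIRS_DEOXY" %in% domains)
    tables$NIRS_DEOXY <- nirs_feature_table(cohort$nirs$DEOXY, cohort$labels,
                                            downsample = downsample)
  results <- list()
  for (d in names(tables)) {
    tab <- tables[[d]]
    eng <- if (d %in% c("NPS", "BIO")) {
      if (!is.null(max_tabular_features) && ncol(tab$x) > max_tabular_features)
        tab <- feature_table(tab$x[, seq_len(max_tabular_features), drop = FALSE],
                             tab$labels, domain = tab$domain,
                             subject_id = tab$subject_id)
      make_engineer("tabular")
    } else {
      make_engineer("nirs", max_features = max_features)
    }
    results[[d]] <- nested_cv(tab, plan, engineer = eng, verbose = verbose)
  }
  results
}

#' Summarize per-domain nested-CV performance as a table
#'
#' One row per domain with accuracy, sensitivity and specificity
#' (mean +/- SD across outer rounds, in %).
#'
#' @param domain_results Named list of `nested_cv_result`s.
#' @return A data.frame with columns `domain`, `accuracy`, `accuracy_sd`,
#'   `sensitivity`, `sensitivity_sd`, `specificity`, `specificity_sd`.
#' @export
performance_table <- function(domain_results) {
  rows <- lapply(names(domain_results), function(d) {
    r <- domain_results[[d]]
    data.frame(domain = d,
               accuracy = 100 * r$mean["accuracy"],
               accuracy_sd = 100 * r$sd["accuracy"],
               sensitivity = 100 * r$mean["sensitivity"],
               sensitivity_sd = 100 * r$sd["sensitivity"],
               specificity = 100 * r$mean["specificity"],
               specificity_sd = 100 * r$sd["specificity"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write classification results as JSON
#'
#' Serializes the per-domain summary, per-round optimal subsets, pooled
#' per-subject predictions and importance profiles, together with the
#' resolved configuration, for audit and reporting.
#'
#' @param domain_results Named list of `nested_cv_result`s.
#' @param path Output JSON path.
#' @param config Optional list of run parameters embedded verbatim.
#' @param ensembles Optional `ensemble_result` to embed.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(domain_results, path, config = NULL,
                               ensembles = NULL) {
  payload <- list(
    package_version = as.character(utils::packageVersion("adhdml")),
    config = config,
    performance = performance_table(domain_results),
    domains = lapply(domain_results, function(r) list(
      metrics = as.data.frame(r$metrics),
      best_subsets = lapply(r$rounds, `[[`, "best_subset"),
      evaluated_count = r$rounds[[1]]$evaluated_count,
      importance = importance(r),
      predictions = r$predictions)))
  if (!is.null(ensembles))
    payload$ensembles <- as.data.frame(ensembles)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
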