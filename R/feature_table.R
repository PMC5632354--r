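#' Construct a subjects-by-features table
#'
#' The shared container moved between every stage of the pipeline: a numeric
#' matrix of subjects by features, binary diagnostic labels, and a domain tag
#' identifying which measurement family the features come from.
#'
#' @param x Numeric matrix, subjects in rows, features in columns. Column
#'   names are kept as feature names (generated as `f1...fk` if absent).
#' @param labels Character or factor vector of `"ADHD"` / `"TD"` labels,
#'   one per row of `x`.
#' @param domain Domain tag: one of `"NPS"`, `"BIO"`, `"NIRS_OXY"`,
#'   `"NIRS_DEOXY"`.
#' @param subject_id Optional subject identifiers; defaults to `s1...sn`.
#' @return An object of class `feature_table`: a list with elements
#'   `subject_id`, `domain`, `x`, `labels`.
#' @export
feature_table <- function(x, labels, domain = c("NPS", "BIO", "NIRS_OXY", "NIRS_DEOXY"),
                          subject_id = NULL) {
  domain <- match.arg(domain)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("one label per subject required (", nrow(x), " rows, ",
         length(labels), " labels)")
  if (anyNA(labels) || !all(labels %in% c("ADHD", "TD")))
    stop("labels must be 'ADHD' or 'TD' with no missing values")
  if (!all(is.finite(x)))
    stop("feature matrix contains non-finite values")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(subject_id))
    subject_id <- paste0("s", seq_len(nrow(x)))
  rownames(x) <- subject_id
  structure(list(subject_id = subject_id, domain = domain,
                 x = x, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> domain:", x$domain, "-", nrow(x$x), "subjects x",
      ncol(x$x), "features (ADHD:", sum(x$labels == "ADHD"),
      "/ TD:", sum(x$labels == "TD"), ")\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset a feature table by subjects
#'
#' @param table A [feature_table()].
#' @param i Row (subject) index.
#' @return A `feature_table` restricted to the selected subjects.
#' @export
subset_subjects <- function(table, i) {
  feature_table(table$x[i, , drop = FALSE], table$labels[i],
                domain = table$domain, subject_id = table$subject_id[i])
}

#' Write / read the feature-table CSV schema
#'
#' The on-disk schema is one row per subject with columns
#' `subject_id`, `label`, then one column per feature.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = table$subject_id, label = table$labels,
                   table$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param domain Domain tag for the table being read.
#' @export
read_feature_table <- function(path, domain = c("NPS", "BIO", "NIRS_OXY", "NIRS_DEOXY")) {
  domain <- match.arg(domain)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df)))
    stop("feature-table CSV must have 'subject_id' and 'label' columns: ", path)
  x <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")), drop = FALSE])
  feature_table(x, df$label, domain = domain, subject_id = df$subject_id)
}
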