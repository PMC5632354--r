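#' Train a linear support vector machine
#'
#' Thin wrapper around a linear-kernel SVM with the regularization constant
#' fixed at its conventional default (`C = 1`, never tuned) and no internal
#' rescaling, so training is deterministic given the data. ADHD is the
#' positive class throughout.
#'
#' @param x Training matrix, subjects x features.
#' @param labels ADHD/TD labels, one per row.
#' @return An object of class `svm_model` wrapping the fit.
#' @export
train_svm <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("ADHD", "TD"))
  if (nlevels(droplevels(labels)) < 2)
    stop("training set must contain both classes")
  fit <- e1071::svm(x, labels, kernel = "linear", cost = 1, scale = FALSE)
  structure(list(fit = fit), class = "svm_model")
}

#' Predict labels (and signed margins) for new subjects
#'
#' @param object An `svm_model`.
#' @param newdata Subjects x features matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels, with the signed decision
#'   values (positive = ADHD side) attached as attribute `"margin"`.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- stats::predict(object$fit, newdata, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # libsvm reports the decision value for "first level vs second level";
  # orient it so positive always means ADHD
  margin <- dv[, 1]
  if (colnames(dv)[1] == "TD/ADHD") margin <- -margin
  out <- as.character(p)
  attr(out, "margin") <- unname(margin)
  out
}
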