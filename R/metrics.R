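#' Classification metrics: accuracy, confusion matrix, ROC/AUC
#'
#' Computes overall accuracy, the confusion matrix (rows = true class,
#' columns = predicted class, over the union of observed classes), and the
#' no-information rate (largest true-class frequency — the accuracy of always
#' predicting the majority class, reported so breakdown toward chance is
#' interpretable on imbalanced data). For binary tasks with scores, a ROC
#' curve is built by sweeping thresholds over the distinct score values (ties
#' grouped) and the AUC computed by the trapezoidal rule.
#'
#' @param truth character/factor vector of true class labels.
#' @param predicted vector of predicted labels, same length.
#' @param scores optional numeric scores (larger = more `positive`); used for
#'   the ROC on binary tasks.
#' @param positive which class counts as positive for the ROC; defaults to
#'   the last of the sorted class labels.
#' @return list with `accuracy`, `no_information_rate`, `confusion` (integer
#'   matrix with class dimnames), and for binary scored tasks `roc` (data
#'   frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
evaluate_classifier <- function(truth, predicted, scores = NULL,
                                positive = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  if (length(unique(truth)) < 2L) {
    stop("need >= 2 classes present in truth", call. = FALSE)
  }
  classes <- sort(unique(c(truth, predicted)))
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes))
  out <- list(
    accuracy = mean(truth == predicted),
    no_information_rate = max(table(truth)) / length(truth),
    confusion = confusion
  )
  if (length(unique(truth)) == 2L && !is.null(scores)) {
    if (length(scores) != length(truth)) {
      stop("scores must match truth in length", call. = FALSE)
    }
    if (is.null(positive)) positive <- sort(unique(truth))[2L]
    roc <- roc_curve(scores, truth == positive)
    out$roc <- roc$points
    out$auc <- roc$auc
    out$positive <- positive
  }
  out
}

# Threshold sweep over distinct scores, ties grouped; trapezoidal AUC.
roc_curve <- function(scores, is_positive) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- is_positive[o]
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  last_of_group <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(y)[last_of_group] / n_pos)
  fpr <- c(0, cumsum(!y)[last_of_group] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(threshold = c(Inf, s[last_of_group]),
                           fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Regression metrics: Spearman's r and RMSE
#'
#' Spearman rank correlation (average ranks for ties) and root-mean-square
#' error between true and predicted values. When either vector is constant
#' the rank correlation is undefined; it is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param truth numeric vector of true values (length >= 3).
#' @param predicted numeric vector of predictions, same length.
#' @return list with `spearman_r`, `rmse`, `degenerate`.
#' @export
evaluate_regressor <- function(truth, predicted) {
  truth <- as.numeric(truth)
  predicted <- as.numeric(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  if (length(truth) < 3L) stop("need >= 3 observations", call. = FALSE)
  degenerate <- stats::sd(truth) == 0 || stats::sd(predicted) == 0
  r <- if (degenerate) 0 else stats::cor(truth, predicted, method = "spearman")
  list(spearman_r = r,
       rmse = sqrt(mean((truth - predicted)^2)),
       degenerate = degenerate)
}
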