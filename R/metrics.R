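# Confusion matrices, one-vs-rest per-class metrics (accuracy, recall,
# precision, specificity, F1 — all in percent), macro averages and ROC/AUC.

#' Confusion matrix
#'
#' @param true,pred equal-length integer label vectors with values in
#'   `0..k-1`.
#' @param k number of classes.
#' @return k x k integer matrix; entry (i, j) counts samples of true class
#'   i-1 predicted as class j-1.
#' @export
confusion <- function(true, pred, k) {
  if (length(true) != length(pred)) {
    stop_kneedhl("label vectors must have equal length", "kneedhl_invalid_input")
  }
  true <- as.integer(true); pred <- as.integer(pred)
  if (length(true) && (any(true < 0 | true >= k) || any(pred < 0 | pred >= k))) {
    stop_kneedhl(sprintf("labels must lie in 0..%d", k - 1), "kneedhl_invalid_input")
  }
  cm <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(true)) cm[true[i] + 1L, pred[i] + 1L] <- cm[true[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' Each class in turn is treated as positive: TP is its diagonal entry, FN
#' the rest of its row, FP the rest of its column, TN everything else. From
#' these, accuracy (TP+TN)/total, recall TP/(TP+FN), precision TP/(TP+FP),
#' specificity TN/(TN+FP) and F1 = 2PR/(P+R) are reported in percent. A zero
#' denominator yields 0 with the class flagged in the `zero_division`
#' attribute rather than NaN.
#'
#' @param cm confusion matrix from [confusion()].
#' @return data.frame with one row per class: tp/fn/fp/tn counts plus
#'   accuracy, recall, precision, specificity, f1 (percent).
#' @export
per_class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0 || nrow(cm) == 0) {
    stop_kneedhl("confusion matrix is empty", "kneedhl_invalid_input")
  }
  k <- nrow(cm)
  flags <- logical(k)
  pct <- function(num, den, c_) {
    if (den == 0) { flags[c_] <<- TRUE; return(0) }
    100 * num / den
  }
  rows <- lapply(seq_len(k), function(c_) {
    tp <- cm[c_, c_]
    fn <- sum(cm[c_, ]) - tp
    fp <- sum(cm[, c_]) - tp
    tn <- total - tp - fn - fp
    recall <- pct(tp, tp + fn, c_)
    precision <- pct(tp, tp + fp, c_)
    f1 <- if (precision + recall == 0) { flags[c_] <<- TRUE; 0 }
          else 2 * precision * recall / (precision + recall)
    data.frame(class = c_ - 1L, tp = tp, fn = fn, fp = fp, tn = tn,
               accuracy = pct(tp + tn, total, c_), recall = recall,
               precision = precision,
               specificity = pct(tn, tn + fp, c_), f1 = f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "zero_division") <- flags
  out
}

#' Overall accuracy from a confusion matrix (percent)
#'
#' @param cm confusion matrix.
#' @return percentage of correctly classified samples.
#' @export
overall_accuracy <- function(cm) {
  100 * sum(diag(as.matrix(cm))) / sum(cm)
}

#' Macro average of per-class metric values
#'
#' @param values numeric vector of per-class percentages.
#' @return their unweighted arithmetic mean.
#' @examples
#' macro_average(c(88, 27, 77, 90, 95)) # 75.4
#' @export
macro_average <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop_kneedhl("need at least one per-class value", "kneedhl_invalid_input")
  }
  mean(values)
}

# Binary ROC by threshold sweep; AUC by the trapezoidal rule. Ties in the
# scores collapse into single staircase vertices, which makes the trapezoid
# equal the rank-average Mann-Whitney statistic.
binary_roc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% c(0, 1)))
  if (!all(is.finite(scores))) {
    stop_kneedhl("ROC scores must be finite", "kneedhl_invalid_input")
  }
  P <- sum(truth == 1); N <- sum(truth == 0)
  if (P == 0 || N == 0) return(NULL)
  ord <- order(scores, decreasing = TRUE)
  t_ord <- truth[ord]; s_ord <- scores[ord]
  cum_tp <- cumsum(t_ord == 1)
  cum_fp <- cumsum(t_ord == 0)
  last_of_tie <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)
  tpr <- c(0, cum_tp[last_of_tie] / P)
  fpr <- c(0, cum_fp[last_of_tie] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(tpr = tpr, fpr = fpr, auc = auc)
}

#' One-vs-rest ROC curves and AUCs
#'
#' For each class, its column of `scores` ranks the samples in a
#' positive-vs-rest problem; AUC is the area under the ROC staircase by the
#' trapezoidal rule (equivalently the rank-average Mann-Whitney statistic).
#' Classes absent from the truth get `NA` and are excluded from the macro
#' average.
#'
#' @param true integer labels in `0..k-1`.
#' @param scores n x k matrix of per-class continuous scores.
#' @param k number of classes.
#' @return list with `per_class` (named AUC vector), `macro` and `curves`
#'   (per-class list of fpr/tpr points).
#' @export
roc_auc <- function(true, scores, k) {
  scores <- as.matrix(scores)
  if (k == 2 && ncol(scores) == 1) {
    scores <- cbind(-scores[, 1], scores[, 1])  # sigmoid score -> two columns
  }
  stopifnot(ncol(scores) == k, nrow(scores) == length(true))
  per <- rep(NA_real_, k)
  curves <- vector("list", k)
  for (c_ in seq_len(k)) {
    r <- binary_roc(as.integer(true == c_ - 1L), scores[, c_])
    if (!is.null(r)) {
      per[c_] <- r$auc
      curves[[c_]] <- r[c("fpr", "tpr")]
    }
  }
  names(per) <- 0:(k - 1)
  list(per_class = per, macro = mean(per, na.rm = TRUE), curves = curves)
}

#' Full evaluation report
#'
#' @param true,pred integer labels in `0..k-1`.
#' @param k number of classes.
#' @param scores optional n x k score matrix for ROC/AUC.
#' @return a `metrics_report`: confusion matrix, per-class table, macro
#'   averages (percent, 1 decimal when printed), overall accuracy, AUCs.
#' @export
metrics_report <- function(true, pred, k, scores = NULL) {
  cm <- confusion(true, pred, k)
  per <- per_class_metrics(cm)
  macro <- list(recall = macro_average(per$recall),
                precision = macro_average(per$precision),
                specificity = macro_average(per$specificity),
                f1 = macro_average(per$f1))
  auc <- if (!is.null(scores)) roc_auc(true, scores, k) else NULL
  structure(list(confusion = cm, per_class = per, macro = macro,
                 accuracy = overall_accuracy(cm), auc = auc, n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: n = %d, accuracy = %.1f%%\n", x$n, x$accuracy))
  df <- x$per_class[, c("class", "recall", "precision", "specificity", "f1")]
  df[, -1] <- round(df[, -1], 1)
  print(df, row.names = FALSE)
  cat(sprintf("macro: recall %.1f  precision %.1f  specificity %.1f  f1 %.1f\n",
              x$macro$recall, x$macro$precision, x$macro$specificity, x$macro$f1))
  if (!is.null(x$auc)) {
    cat("AUC per class:", paste(sprintf("%.3f", x$auc$per_class), collapse = " "),
        sprintf(" macro %.3f\n", x$auc$macro))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @param extra named list merged into the JSON (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, extra = list()) {
  obj <- c(list(
    n = report$n,
    accuracy = report$accuracy,
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    macro = report$macro,
    auc = if (!is.null(report$auc)) {
      list(per_class = report$auc$per_class, macro = report$auc$macro)
    }
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
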