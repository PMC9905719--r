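#' Evaluate predicted against actual quality classes
#'
#' From the confusion matrix over the union of classes present, computes:
#' overall accuracy (sum of true positives over the number of samples),
#' per-class precision `TP / (TP + FP)` and recall `TP / (TP + FN)` with
#' their macro averages (micro averages, which equal accuracy for
#' single-label classification, are also reported), and the root mean
#' square error on the ordinal class encoding I -> 1 ... poor V -> 6:
#' `rmse = sqrt(mean((predicted - actual)^2))`.
#'
#' A class never predicted (`TP + FP = 0`) gets precision 0 with a logged
#' note; classes absent from both vectors do not enter the macro averages.
#'
#' @param actual,predicted Equal-length label vectors (integers 1..6 or
#'   values coercible to them).
#' @return A `wq_metrics` list: `accuracy`, `precision`, `recall` (macro),
#'   `rmse`, `micro_precision`, `micro_recall`, `per_class` data frame
#'   (class, tp, fp, tn, fn, precision, recall) and the `confusion` matrix.
#' @export
#' @examples
#' evaluate_classification(c(1, 1, 2, 2), c(1, 2, 2, 2))
evaluate_classification <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stopf("actual and predicted differ in length")
  }
  if (length(actual) < 1L) stopf("need at least one sample")
  a <- as.integer(as.character(actual))
  p <- as.integer(as.character(predicted))
  if (anyNA(a) || anyNA(p)) stopf("labels must be integer class ids")
  k <- length(a)
  classes <- sort(unique(c(a, p)))
  af <- factor(a, levels = classes)
  pf <- factor(p, levels = classes)
  confusion <- table(actual = af, predicted = pf)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- k - tp - fp - fn
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  if (any(tp + fp == 0)) {
    wq_note("metrics", "class(es) ", paste(classes[tp + fp == 0], collapse = ", "),
            " never predicted; precision set to 0")
  }
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  per_class <- data.frame(class = classes, tp = as.integer(tp),
                          fp = as.integer(fp), tn = as.integer(tn),
                          fn = as.integer(fn), precision = as.numeric(prec),
                          recall = as.numeric(rec), row.names = NULL)
  structure(list(
    accuracy = sum(tp) / k,
    precision = mean(prec),
    recall = mean(rec),
    rmse = sqrt(mean((p - a)^2)),
    micro_precision = sum(tp) / (sum(tp) + sum(fp)),
    micro_recall = sum(tp) / (sum(tp) + sum(fn)),
    n = k,
    per_class = per_class,
    confusion = confusion
  ), class = "wq_metrics")
}

#' @export
print.wq_metrics <- function(x, ...) {
  cat(sprintf(
    "Classification metrics on %d samples\n  accuracy  %.4f\n  precision %.4f (macro)\n  recall    %.4f (macro)\n  rmse      %.4f (ordinal classes)\n",
    x$n, x$accuracy, x$precision, x$recall, x$rmse))
  invisible(x)
}

# Flat data frame for report files: overall row then per-class rows.
metrics_report <- function(m) {
  overall <- data.frame(class = "overall", precision = m$precision,
                        recall = m$recall, accuracy = m$accuracy,
                        rmse = m$rmse, row.names = NULL)
  per <- data.frame(class = as.character(m$per_class$class),
                    precision = m$per_class$precision,
                    recall = m$per_class$recall,
                    accuracy = NA_real_, rmse = NA_real_, row.names = NULL)
  rbind(overall, per)
}
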