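# One-vs-rest evaluation metrics.
#
# "Specificity" here is the true-negative rate TN/(TN+FP); precision
# TP/(TP+FP) is reported separately because parts of the gene-finding
# literature use "specificity" for precision.

#' One-vs-rest confusion summary
#'
#' Aligns predictions and truth by id and computes, for every class, the
#' one-vs-rest confusion counts and the derived rates, plus the overall
#' multi-class accuracy.
#'
#' @param predictions Named character vector (names = ids) or data frame
#'   with columns `id`, `label`.
#' @param truth Same format as `predictions`.
#' @return Object of class `confusion_summary`: `per_class` data frame
#'   (class, TP, FP, TN, FN, sensitivity, specificity, precision,
#'   accuracy) and `overall_accuracy`.
#' @export
compute_metrics <- function(predictions, truth) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.character(x$label),
                                          as.character(x$id))
    else x
  }
  pred <- as_vec(predictions)
  tru <- as_vec(truth)
  if (length(pred) == 0) stop("empty prediction set", call. = FALSE)
  if (!setequal(names(pred), names(tru)) ||
      length(pred) != length(tru)) {
    stop("prediction and truth ids do not align", call. = FALSE)
  }
  pred <- pred[names(tru)]
  classes <- sort(unique(c(pred, tru)))
  n <- length(tru)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & tru == cl)
    fp <- sum(pred == cl & tru != cl)
    fn <- sum(pred != cl & tru == cl)
    tn <- n - tp - fp - fn
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               accuracy = (tp + tn) / n,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_class = per,
                 overall_accuracy = mean(pred == tru)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  invisible(x)
}
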