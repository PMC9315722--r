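#' Confusion counts for binary classification
#'
#' Tallies true/false positives and negatives, with the case class (label 1)
#' as positive.
#'
#' @param truth integer 0/1 vector of true labels.
#' @param predicted integer 0/1 vector of predicted labels.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stopf("truth and predicted must have equal length")
  if (!is_binary_label(truth) || !is_binary_label(predicted))
    stopf("labels must be 0/1 with no missing values")
  structure(
    list(TP = sum(truth == 1L & predicted == 1L),
         FP = sum(truth == 0L & predicted == 1L),
         TN = sum(truth == 0L & predicted == 0L),
         FN = sum(truth == 1L & predicted == 0L)),
    class = "confusion_counts"
  )
}

#' @exportS3Method base::print
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Five classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 score, all
#' as percentages:
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `PRE = TP/(TP+FP)`, `REC = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`, `F1 = 2*PRE*REC/(PRE+REC)`. A metric whose
#' denominator is zero is reported as 0 and flagged `undefined` rather than
#' returned as `NaN`.
#'
#' @param counts a [confusion_counts()] object, or anything coercible via
#'   `confusion_counts(truth, predicted)` when `predicted` is supplied.
#' @param predicted optional: if given, `counts` is interpreted as the truth
#'   vector.
#' @return Object of class `classification_metrics`: named list with `acc`,
#'   `pre`, `rec`, `spe`, `f1` (percent, in `[0, 100]`) and a logical
#'   `undefined` flag vector.
#' @examples
#' m <- classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
#' m$acc
#' @export
classification_metrics <- function(counts, predicted = NULL) {
  if (!is.null(predicted)) counts <- confusion_counts(counts, predicted)
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0L) stopf("no evaluated subjects: all counts are zero")
  ratio <- function(num, den) {
    if (den == 0) list(v = 0, undef = TRUE) else list(v = 100 * num / den, undef = FALSE)
  }
  pre <- ratio(counts$TP, counts$TP + counts$FP)
  rec <- ratio(counts$TP, counts$TP + counts$FN)
  spe <- ratio(counts$TN, counts$TN + counts$FP)
  f1 <- if (pre$v + rec$v == 0) list(v = 0, undef = TRUE)
        else list(v = 2 * pre$v * rec$v / (pre$v + rec$v), undef = FALSE)
  structure(
    list(acc = 100 * (counts$TP + counts$TN) / total,
         pre = pre$v, rec = rec$v, spe = spe$v, f1 = f1$v,
         undefined = c(acc = FALSE, pre = pre$undef, rec = rec$undef,
                       spe = spe$undef, f1 = f1$undef),
         counts = counts),
    class = "classification_metrics"
  )
}

#' @exportS3Method base::print
print.classification_metrics <- function(x, digits = 2, ...) {
  v <- unlist(x[c("acc", "pre", "rec", "spe", "f1")])
  names(v) <- c("ACC", "PRE", "REC", "SPE", "F1")
  lab <- sprintf("%.*f%%%s", digits, v,
                 ifelse(x$undefined, " (undefined, reported as 0)", ""))
  cat(paste(sprintf("%-4s %s", names(v), lab), collapse = "\n"), "\n")
  invisible(x)
}

metric_names <- c("acc", "pre", "rec", "spe", "f1")
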