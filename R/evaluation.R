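# Confusion matrix and the binary-classification metric suite.
#
# Class convention: "complaint" is the positive class, "other" the
# negative class. Precision and recall in the summary report are MACRO
# averages over the two classes (balanced accuracy is then identical to
# macro recall); per-class values are reported alongside.

#' Build a 2x2 confusion matrix
#'
#' @param predictions Either a prediction tibble with `true` and
#'   `predicted` columns (as pooled by [crossval_train()]), or the four
#'   counts directly via `confusion_matrix()`.
#' @return A `confusion_2x2`: list `tn`, `fp`, `fn`, `tp`.
#' @export
confusion <- function(predictions) {
  if (!all(c("true", "predicted") %in% names(predictions)) ||
      anyNA(predictions$true)) {
    stop("predictions must carry both true and predicted labels", call. = FALSE)
  }
  tr <- predictions$true
  pr <- predictions$predicted
  confusion_matrix(tn = sum(tr == "other" & pr == "other"),
                   fp = sum(tr == "other" & pr == "complaint"),
                   fn = sum(tr == "complaint" & pr == "other"),
                   tp = sum(tr == "complaint" & pr == "complaint"))
}

#' @rdname confusion
#' @param tn,fp,fn,tp Cell counts (true-negative, false-positive,
#'   false-negative, true-positive; "complaint" is positive).
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(cells < 0) || anyNA(cells)) stop("counts must be nonnegative", call. = FALSE)
  structure(as.list(cells), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(true = c("other", "complaint"),
                              predicted = c("other", "complaint")))
  print(m)
  invisible(x)
}

#' Full metric suite from a confusion matrix
#'
#' Computes accuracy, balanced accuracy, macro/micro/weighted F1, the
#' Matthews correlation coefficient, and macro-averaged precision and
#' recall (per-class values attached). For binary single-label data,
#' micro F1 equals accuracy and balanced accuracy equals macro recall by
#' construction. A zero MCC denominator (a degenerate all-one-class
#' prediction or truth) is reported as `mcc = 0` with `mcc_undefined =
#' TRUE` rather than as an error.
#'
#' @param cm A `confusion_2x2`.
#' @return A `metrics_report` list.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_2x2"))
  tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  total <- tn + fp + fn + tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec_c <- div(tp, tp + fp); prec_o <- div(tn, tn + fn)
  rec_c <- div(tp, tp + fn); rec_o <- div(tn, tn + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  f1_c <- f1(prec_c, rec_c); f1_o <- f1(prec_o, rec_o)
  n_c <- tp + fn; n_o <- tn + fp
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_undefined <- mcc_den == 0
  structure(list(
    accuracy = (tp + tn) / total,
    balanced_accuracy = (rec_c + rec_o) / 2,
    f1_macro = (f1_c + f1_o) / 2,
    f1_micro = (tp + tn) / total,
    f1_weighted = (n_c * f1_c + n_o * f1_o) / total,
    mcc = if (mcc_undefined) 0 else (tp * tn - fp * fn) / mcc_den,
    mcc_undefined = mcc_undefined,
    precision_macro = (prec_c + prec_o) / 2,
    recall_macro = (rec_c + rec_o) / 2,
    per_class = list(
      complaint = list(precision = prec_c, recall = rec_c, f1 = f1_c, n = n_c),
      other = list(precision = prec_o, recall = rec_o, f1 = f1_o, n = n_o))
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  show <- c(accuracy = x$accuracy, `balanced accuracy` = x$balanced_accuracy,
            `F1 macro` = x$f1_macro, `F1 micro` = x$f1_micro,
            `F1 weighted` = x$f1_weighted, MCC = x$mcc,
            precision = x$precision_macro, recall = x$recall_macro)
  for (nm in names(show)) cat(sprintf("%-18s %.4f\n", nm, round(show[[nm]], 4)))
  if (x$mcc_undefined) cat("(MCC undefined; reported as 0)\n")
  invisible(x)
}

#' Misclassification rate
#'
#' The share of items wrongly classified: `(fp + fn) / total`, i.e.
#' `1 - accuracy`.
#'
#' @param cm A `confusion_2x2`.
#' @return A single number in `[0, 1]`.
#' @export
misclassification_rate <- function(cm) {
  stopifnot(inherits(cm, "confusion_2x2"))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  (cm$fp + cm$fn) / total
}
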