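# Evaluation statistics from a 7x7 confusion matrix: per-class one-vs-rest
# accuracy, sensitivity (recall), specificity, precision, F1 and Matthews
# correlation, plus unweighted macro averages.

#' Confusion matrix from label vectors
#'
#' @param truth,pred Vectors of class labels (factors or characters).
#' @param classes Class order; defaults to [lesion_classes()] when all
#'   labels belong to it, otherwise the sorted union.
#' @return Square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop("truth and pred lengths differ")
  if (is.null(classes)) {
    u <- union(truth, pred)
    classes <- if (all(u %in% lesion_classes())) lesion_classes() else sort(u)
  }
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, pred = classes))
  m
}

#' One-vs-rest binary counts for one class
#'
#' Reduces a multiclass confusion matrix to the binary TP/FN/FP/TN counts
#' of class `k`: TP is the diagonal entry, FN the rest of row `k`, FP the
#' rest of column `k`, and TN everything else.
#'
#' @param cm Square confusion matrix (rows = truth).
#' @param k Class index (1-based) or class name.
#' @return List with integer fields `TP`, `FN`, `FP`, `TN`.
#' @export
#' @examples
#' binarize(matrix(c(5, 2, 1, 3), 2, byrow = TRUE), 1)
binarize <- function(cm, k) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (is.character(k)) k <- match(k, rownames(cm))
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(TP = as.numeric(tp), FN = as.numeric(fn),
       FP = as.numeric(fp), TN = as.numeric(tn))
}

ratio_or_zero <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Binary classification metrics
#'
#' Computes the six statistics from one set of binary counts:
#' accuracy `(TP+TN)/(TP+TN+FP+FN) x 100`, sensitivity/recall
#' `TP/(TP+FN) x 100`, specificity `TN/(TN+FP) x 100`, precision
#' `TP/(TP+FP) x 100`, F1 `2 pr / (p + r)` on the fractional scale, and
#' Matthews correlation `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any ratio with a zero denominator is reported as 0 with a warning, which
#' keeps macro averages defined for classes absent from a fold.
#'
#' @param b Counts from [binarize()], or a list with `TP`, `FN`, `FP`, `TN`.
#' @return Named numeric vector `acc`, `se`, `sp`, `pr` (percent scale,
#'   0-100), `f1` (0-1) and `mcc` (-1..1).
#' @export
#' @examples
#' compute_metrics(list(TP = 50, TN = 40, FP = 10, FN = 5))
compute_metrics <- function(b) {
  tp <- b$TP; tn <- b$TN; fp <- b$FP; fn <- b$FN
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples in binary counts")
  acc <- 100 * (tp + tn) / total
  se <- 100 * ratio_or_zero(tp, tp + fn, "sensitivity")
  sp <- 100 * ratio_or_zero(tn, tn + fp, "specificity")
  pr <- 100 * ratio_or_zero(tp, tp + fp, "precision")
  p <- pr / 100; r <- se / 100
  f1 <- if (p + r == 0) {
    warning("F1 undefined (zero precision and recall); reporting 0",
            call. = FALSE)
    0
  } else 2 * p * r / (p + r)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) {
    warning("MCC undefined (zero denominator); reporting 0", call. = FALSE)
    0
  } else (tp * tn - fp * fn) / den
  c(acc = acc, se = se, sp = sp, pr = pr, f1 = f1, mcc = mcc)
}

#' Per-class and macro metrics report
#'
#' Applies [binarize()] and [compute_metrics()] to every class of a
#' multiclass confusion matrix and macro-averages (unweighted mean over
#' classes). Overall accuracy is additionally reported as
#' `trace / total x 100`.
#'
#' @param cm Square confusion matrix, rows = true class.
#' @return An object of class `metrics_report`: list with `per_class`
#'   (data.frame, one row per class), `macro` (named vector), and
#'   `overall_accuracy`.
#' @export
macro_report <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (sum(cm) == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  per <- t(vapply(seq_len(nrow(cm)),
                  function(k) compute_metrics(binarize(cm, k)),
                  numeric(6)))
  per_df <- data.frame(class = classes, per, row.names = NULL)
  rep <- list(per_class = per_df,
              macro = colMeans(per),
              overall_accuracy = 100 * sum(diag(cm)) / sum(cm))
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (acc/se/sp/pr on 0-100, f1 on 0-1, mcc on -1..1):\n")
  print(cbind(x$per_class[1],
              round(x$per_class[-1], 3)), row.names = FALSE)
  m <- round(x$macro, 3)
  cat("Macro:  ", paste(names(m), m, sep = "=", collapse = "  "), "\n")
  cat(sprintf("Overall accuracy: %.3f%%\n", x$overall_accuracy))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' JSON for the full report and CSV for the per-class table; the percent
#' views of F1 and MCC (x100) are included alongside the canonical
#' fractional values.
#'
#' @param report A [macro_report()] result.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  per <- report$per_class
  per$f1_pct <- 100 * per$f1
  per$mcc_pct <- 100 * per$mcc
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_class = per,
                              macro = as.list(report$macro),
                              overall_accuracy = report$overall_accuracy),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(per, csv_path, row.names = FALSE)
  invisible(report)
}
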