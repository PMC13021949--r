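#' Confusion matrix
#'
#' @param labels,predictions aligned character vectors of true and predicted
#'   classes, all within `class_order`.
#' @param class_order ordered class list defining rows/columns.
#' @return C x C integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(labels, predictions, class_order) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must be aligned")
  bad <- setdiff(unique(c(labels, predictions)), class_order)
  if (length(bad))
    stop("label(s) outside class_order: ", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = class_order),
               factor(predictions, levels = class_order))
  m <- matrix(as.integer(tab), nrow = length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  m
}

#' Per-class precision, recall and F1 (one-vs-rest)
#'
#' For each class i the confusion matrix is collapsed one-vs-rest:
#' `Pre = TP / (TP + FP)`, `Re = TP / (TP + FN)`, F1 their harmonic mean.
#' Division by zero yields 0 with a warning.
#'
#' @param cm confusion matrix from [confusion()].
#' @return data frame: class, support, precision, recall, f1.
#' @export
per_class_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) == 0)
    stop("cm must be a non-empty square confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(classes[den == 0], collapse = ", "), "; reported as 0")
    out
  }
  pre <- safe_div(tp, tp + fp, "precision")
  re <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(pre + re > 0, 2 * pre * re / (pre + re), 0)
  data.frame(class = classes, support = rowSums(cm), precision = pre,
             recall = re, f1 = f1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Support-weighted F1 score
#'
#' `F1 = sum_i beta_i * F1_i` with `beta_i = support_i / n`.
#'
#' @param f1 per-class F1 values.
#' @param supports per-class true-sample counts (positive sum).
#' @return scalar.
#' @export
weighted_f1 <- function(f1, supports) {
  if (sum(supports) <= 0) stop("supports must have positive sum")
  sum(f1 * supports / sum(supports))
}

#' Matthews correlation coefficient
#'
#' The multiclass generalization (correlation between true and predicted
#' one-hot assignments); for two classes it reduces exactly to the familiar
#' binary formula `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' An undefined denominator (e.g. all predictions in one class) yields 0
#' with a warning.
#'
#' @param cm confusion matrix from [confusion()].
#' @return scalar in \[-1, 1\].
#' @export
mcc <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) == 0)
    stop("cm must be a non-empty square confusion matrix")
  cm <- matrix(as.numeric(cm), nrow(cm))
  n <- sum(cm)
  tr <- sum(diag(cm))
  tk <- rowSums(cm)      # true counts
  pk <- colSums(cm)      # predicted counts
  num <- tr * n - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) {
    warning("undefined MCC denominator; reported as 0")
    return(0)
  }
  num / den
}

# midrank-based binary ranking AUC (Mann-Whitney)
binary_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multiclass AUC
#'
#' For each class, the ranking AUC of that class's predicted probability
#' against binarized truth (ties handled by midranks), averaged over
#' classes: macro (unweighted, default) or support-weighted. Classes absent
#' from the labels are skipped with a warning.
#'
#' @param labels character vector of true classes.
#' @param probs matrix of class probabilities, columns in `class_order`
#'   order, rows summing to 1.
#' @param class_order ordered class list.
#' @param average `"macro"` or `"weighted"`.
#' @return scalar AUC.
#' @export
multiclass_auc <- function(labels, probs, class_order,
                           average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (nrow(probs) != length(labels))
    stop("probs rows must align with labels")
  if (ncol(probs) != length(class_order))
    stop("probs must have one column per class")
  aucs <- w <- numeric(0)
  for (i in seq_along(class_order)) {
    pos <- labels == class_order[i]
    if (!any(pos)) {
      warning("class ", class_order[i], " absent from labels; skipped")
      next
    }
    a <- binary_auc(probs[, i], pos)
    if (!is.na(a)) { aucs <- c(aucs, a); w <- c(w, sum(pos)) }
  }
  if (length(aucs) == 0) stop("no class with both positives and negatives")
  if (average == "macro") mean(aucs) else sum(aucs * w / sum(w))
}

#' Full evaluation report
#'
#' Confusion matrix, accuracy, per-class precision/recall/F1, weighted F1,
#' Matthews correlation and one-vs-rest AUC in one object.
#'
#' @param labels,predictions aligned true and predicted classes.
#' @param probs optional probability matrix (enables AUC).
#' @param class_order ordered class list.
#' @return object of class `"metrics_report"`.
#' @export
metrics_report <- function(labels, predictions, probs = NULL, class_order) {
  cm <- confusion(labels, predictions, class_order)
  per <- per_class_metrics(cm)
  rep <- list(confusion = cm,
              accuracy = sum(diag(cm)) / sum(cm),
              per_class = per,
              weighted_f1 = weighted_f1(per$f1, per$support),
              mcc = mcc(cm),
              auc = if (!is.null(probs))
                multiclass_auc(labels, probs, class_order) else NA_real_,
              class_order = class_order, n = sum(cm))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples (%d classes)\n", x$n,
              length(x$class_order)))
  cat("\nConfusion matrix (rows = true):\n")
  print(x$confusion)
  per <- x$per_class
  per[c("precision", "recall", "f1")] <-
    lapply(per[c("precision", "recall", "f1")], round, 2)
  cat("\n"); print(per, row.names = FALSE)
  cat(sprintf("\naccuracy %.2f | weighted F1 %.2f | MCC %.2f",
              round(x$accuracy, 2), round(x$weighted_f1, 2),
              round(x$mcc, 2)))
  if (!is.na(x$auc)) cat(sprintf(" | OvR AUC %.2f", round(x$auc, 2)))
  cat("\n")
  invisible(x)
}

#' Write a metrics report as delimited text
#'
#' @param report a [metrics_report()].
#' @param dir output directory (summary, per-class table, confusion matrix).
#' @return Invisibly, `dir`.
#' @export
write_metrics_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$per_class, file.path(dir, "per_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$confusion, file.path(dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  summ <- data.frame(metric = c("n", "accuracy", "weighted_f1", "mcc", "auc"),
                     value = c(report$n, report$accuracy,
                               report$weighted_f1, report$mcc, report$auc))
  utils::write.table(summ, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
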