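# Evaluation: confusion matrices, per-class precision, macro AP, micro AC.
#
# Precision of class i is TP_i / (TP_i + FP_i), with TP_i the confusion
# diagonal and FP_i the off-diagonal column sum. AP (Average Precision)
# is the unweighted mean of the defined per-class precisions; AC (Average
# Count) is total TP over total predictions, i.e. micro accuracy when
# every sample receives one prediction. A REJECT prediction occupies a
# predicted-only column: it contributes errors to AC but defines no
# precision of its own.

#' Build a confusion matrix
#'
#' Rows index the target (true) class, columns the predicted class. The
#' reserved `REJECT` label may appear among predictions only; when present
#' it becomes an extra predicted-only column.
#'
#' @param true_labels character vector of true class labels.
#' @param predicted_labels character vector of predictions, same length;
#'   may contain [reject_label()].
#' @param label_order ordered class labels; defaults to the sorted union
#'   of true labels.
#' @return an object of class `confusion_matrix` with elements `labels`,
#'   `pred_labels` and `counts` (integer matrix).
#' @export
confusion <- function(true_labels, predicted_labels, label_order = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors differ in length (",
         length(true_labels), " vs ", length(predicted_labels), ")",
         call. = FALSE)
  }
  if (is.null(label_order)) label_order <- sort(unique(true_labels))
  bad_true <- setdiff(unique(true_labels), label_order)
  if (length(bad_true)) {
    stop("true labels outside label order: ", paste(bad_true, collapse = ", "),
         call. = FALSE)
  }
  pred_order <- label_order
  if (reject_label() %in% predicted_labels &&
      !reject_label() %in% pred_order) {
    pred_order <- c(pred_order, reject_label())
  }
  bad_pred <- setdiff(unique(predicted_labels), pred_order)
  if (length(bad_pred)) {
    stop("predicted labels outside label order: ",
         paste(bad_pred, collapse = ", "), call. = FALSE)
  }
  counts <- table(
    factor(true_labels, levels = label_order),
    factor(predicted_labels, levels = pred_order)
  )
  counts <- matrix(as.integer(counts), nrow = length(label_order),
                   dimnames = list(label_order, pred_order))
  structure(
    list(labels = label_order, pred_labels = pred_order, counts = counts),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>", sum(x$counts), "samples,",
      length(x$labels), "target classes\n")
  print(x$counts)
  invisible(x)
}

#' Per-class precision from a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector of precisions in \[0, 1\]; a class that is
#'   never predicted has precision `NA` (undefined, not zero). The
#'   REJECT column, if any, carries no precision.
#' @export
precision_per_class <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  out <- stats::setNames(rep(NA_real_, length(cm$labels)), cm$labels)
  for (lbl in cm$labels) {
    if (!lbl %in% cm$pred_labels) next
    col_total <- sum(cm$counts[, lbl])
    tp <- if (lbl %in% rownames(cm$counts)) cm$counts[lbl, lbl] else 0L
    out[lbl] <- if (col_total > 0) tp / col_total else NA_real_
  }
  out
}

#' Average Precision (macro mean of per-class precisions)
#'
#' @param per_class named numeric vector as returned by
#'   [precision_per_class()]; `NA` entries (never-predicted classes) are
#'   excluded with a warning.
#' @return the unweighted mean of the defined precisions.
#' @export
average_precision <- function(per_class) {
  defined <- per_class[!is.na(per_class)]
  if (!length(defined)) {
    stop("no class has a defined precision; AP is undefined", call. = FALSE)
  }
  if (anyNA(per_class)) {
    warning("excluding ", sum(is.na(per_class)),
            " never-predicted class(es) from AP: ",
            paste(names(per_class)[is.na(per_class)], collapse = ", "),
            call. = FALSE)
  }
  mean(defined)
}

#' Average Count (micro accuracy)
#'
#' Total true positives over total predictions; equals plain accuracy when
#' each sample receives exactly one prediction.
#'
#' @param cm a `confusion_matrix`.
#' @return a number in \[0, 1\].
#' @export
average_count <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  shared <- intersect(rownames(cm$counts), colnames(cm$counts))
  sum(cm$counts[cbind(shared, shared)]) / total
}

#' Relative improvement between two scores, in percent
#'
#' @param before,after scores on the same scale; `before` must be > 0.
#' @return `100 * (after - before) / before`.
#' @export
relative_improvement <- function(before, after) {
  if (any(before <= 0)) stop("baseline score must be positive", call. = FALSE)
  100 * (after - before) / before
}

#' Full evaluation report
#'
#' @inheritParams confusion
#' @return an object of class `metrics_report`: the confusion matrix,
#'   per-class precision, `AP` (`NA` when no class has a defined
#'   precision), `AC` and `n_samples`.
#' @export
metrics_report <- function(true_labels, predicted_labels, label_order = NULL) {
  cm <- confusion(true_labels, predicted_labels, label_order)
  per_class <- precision_per_class(cm)
  ap <- tryCatch(suppressWarnings(average_precision(per_class)),
                 error = function(e) NA_real_)
  structure(
    list(
      confusion = cm,
      per_class_precision = per_class,
      AP = ap,
      AC = average_count(cm),
      n_samples = sum(cm$counts)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, AC = %.2f%%, AP = %.2f%%\n",
              x$n_samples, 100 * x$AC, 100 * x$AP))
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Emits `<stem>_per_class.csv` (per-class precision),
#' `<stem>_confusion.csv` and `<stem>_summary.json` (AC, AP, n).
#'
#' @param report a `metrics_report`.
#' @param stem output path stem.
#' @export
write_metrics_report <- function(report, stem) {
  per_class <- data.frame(
    class = names(report$per_class_precision),
    precision = unname(report$per_class_precision)
  )
  utils::write.csv(per_class, paste0(stem, "_per_class.csv"),
                   row.names = FALSE)
  cm_df <- as.data.frame.matrix(report$confusion$counts)
  cm_df <- cbind(true_class = rownames(report$confusion$counts), cm_df)
  utils::write.csv(cm_df, paste0(stem, "_confusion.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(AC = report$AC, AP = report$AP, n_samples = report$n_samples),
    paste0(stem, "_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}
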