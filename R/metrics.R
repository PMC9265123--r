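#' Confusion matrix with a fixed class order
#'
#' @param true_labels,predicted_labels Equal-length label vectors; every
#'   label must appear in `class_order`.
#' @param class_order Character vector fixing row/column order.
#' @return C x C integer matrix; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  stopifnot(length(true_labels) == length(predicted_labels))
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(unknown) > 0) {
    stop("label(s) not in class_order: ", paste(unknown, collapse = ", "))
  }
  tab <- table(factor(true_labels, levels = class_order),
               factor(predicted_labels, levels = class_order))
  M <- matrix(as.integer(tab), length(class_order), length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  M
}

#' Column-normalize a confusion matrix
#'
#' Divides every column by its sum, so each nonzero column sums to 1
#' (the distribution of true classes among items predicted as that class).
#' All-zero columns are left at zero rather than producing NaN.
#'
#' @param confusion Count matrix.
#' @return Real matrix of the same shape.
#' @export
column_normalize <- function(confusion) {
  cs <- colSums(confusion)
  cs[cs == 0] <- 1
  sweep(confusion, 2, cs, "/")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return F1 = 2PR / (P + R), elementwise; 0 where both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  denom <- precision + recall
  ifelse(denom > 0, 2 * precision * recall / denom, 0)
}

#' Per-class and averaged classification metrics from a confusion matrix
#'
#' Derives one-vs-rest TP/FP/FN per class, then precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2TP/(2TP+FP+FN) (the harmonic mean of
#' precision and recall), overall accuracy = trace/total, and macro
#' (unweighted) and support-weighted averages. Precision or recall with a
#' zero denominator is reported as 0 and flagged.
#'
#' @param confusion Square count matrix (rows true, columns predicted), or
#'   `NULL` to build one from `true_labels`/`predicted_labels`.
#' @param class_order Class order; defaults to the confusion matrix dimnames.
#' @param true_labels,predicted_labels Optional label vectors used when
#'   `confusion` is `NULL`.
#' @param unit Free-text evaluation unit recorded in the report (e.g.
#'   `"graphs"` or `"aberrations"`).
#' @return Object of class `eval_report`: list with `confusion`,
#'   `per_class` (data frame label/precision/recall/f1/support),
#'   `accuracy`, `macro`, `weighted`, `class_order`, `unit`,
#'   `zero_division` flag.
#' @export
classification_report <- function(confusion = NULL, class_order = NULL,
                                  true_labels = NULL, predicted_labels = NULL,
                                  unit = "graphs") {
  if (is.null(confusion)) {
    if (is.null(class_order)) {
      class_order <- sort(unique(as.character(true_labels)))
    }
    confusion <- confusion_matrix(true_labels, predicted_labels, class_order)
  }
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square")
  }
  if (is.null(class_order)) class_order <- rownames(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  support <- rowSums(confusion)
  total <- sum(confusion)
  zero_div <- any(tp + fp == 0) || any(tp + fn == 0)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  wmean <- function(x) {
    if (total == 0) 0 else sum(x * support) / total
  }
  structure(
    list(
      confusion = confusion,
      per_class = data.frame(label = class_order, precision = precision,
                             recall = recall, f1 = f1, support = support,
                             stringsAsFactors = FALSE, row.names = NULL),
      accuracy = if (total == 0) 0 else sum(tp) / total,
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      weighted = c(precision = wmean(precision), recall = wmean(recall),
                   f1 = wmean(f1)),
      class_order = class_order,
      unit = unit,
      zero_division = zero_div
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat("<eval_report> evaluation unit:", x$unit, "\n")
  pc <- x$per_class
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy: %.*f\n", digits, x$accuracy))
  cat(sprintf("macro    P/R/F1: %.*f / %.*f / %.*f\n",
              digits, x$macro["precision"], digits, x$macro["recall"],
              digits, x$macro["f1"]))
  cat(sprintf("weighted P/R/F1: %.*f / %.*f / %.*f\n",
              digits, x$weighted["precision"], digits, x$weighted["recall"],
              digits, x$weighted["f1"]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  doc <- list(
    unit = report$unit,
    class_order = report$class_order,
    confusion = unname(apply(report$confusion, 1, as.list)),
    per_class = report$per_class,
    accuracy = report$accuracy,
    macro = as.list(report$macro),
    weighted = as.list(report$weighted)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write confusion matrices (counts and column-normalized) as TSV
#'
#' @param report An `eval_report`.
#' @param counts_path,normalized_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_confusion_tsv <- function(report, counts_path, normalized_path) {
  utils::write.table(report$confusion, counts_path, sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(column_normalize(report$confusion), normalized_path,
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(c(counts_path, normalized_path))
}
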