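# Evaluation: confusion matrix, accuracy / precision / recall / F1,
# Cohen's kappa, and the cubed-error Test Cost Index.

as_stage_factor <- function(x) {
  x <- as.character(x)
  bad <- !(x %in% stages())
  if (any(bad)) {
    stop("unknown stage label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = stages())
}

#' Confusion matrix over the five sleep stages
#'
#' Rows are true stages, columns predicted, both in the fixed order
#' W, S1, S2, S3, REM.
#'
#' @param true_labels,predicted_labels Equal-length character vectors of
#'   canonical stage labels.
#' @return A 5x5 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(predicted_labels), ")", call. = FALSE)
  }
  cm <- table(true = as_stage_factor(true_labels),
              predicted = as_stage_factor(predicted_labels))
  structure(unclass(cm), class = c("confusion_matrix", "matrix"))
}

#' Per-class and overall accuracy, precision, recall, F1
#'
#' Each class is scored one-vs-rest: with its TP/FP/FN/TN counts,
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean, and
#' per-class accuracy = (TP+TN)/total. Overall accuracy is the diagonal
#' fraction. A class with no predicted (or true) instances gets precision
#' (recall) 0 with a warning. All rates are percentages.
#'
#' @param cm A [confusion()] matrix (any square labelled count matrix works).
#' @return List with `per_class` (data frame: class, precision, recall, f1,
#'   accuracy), `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
basic_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  div0 <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0)) {
      warning("class(es) with no ", what, " instances: ",
              paste(classes[den == 0], collapse = ", "),
              "; reporting 0", call. = FALSE)
    }
    out
  }
  prec <- div0(tp, tp + fp, "predicted")
  rec <- div0(tp, tp + fn, "true")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  per_class <- data.frame(
    class = classes,
    precision = 100 * prec,
    recall = 100 * rec,
    f1 = 100 * f1,
    accuracy = 100 * (tp + tn) / total,
    row.names = NULL
  )
  list(per_class = per_class,
       accuracy = 100 * sum(tp) / total,
       macro_precision = 100 * mean(prec),
       macro_recall = 100 * mean(rec),
       macro_f1 = 100 * mean(f1))
}

#' Cohen's kappa
#'
#' `kappa = (p0 - pe) / (1 - pe)` with observed agreement `p0` the diagonal
#' fraction and chance agreement `pe` the product of the marginals.
#'
#' @param cm A [confusion()] matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  p0 <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-15) {
    stop("degenerate marginals (pe = 1); kappa undefined", call. = FALSE)
  }
  (p0 - pe) / (1 - pe)
}

#' Test Cost Index
#'
#' Mean cubed signed difference between true and predicted stage codes,
#' `TCI = mean((y - y_hat)^3)`, with the fixed encoding W=0, S1=1, S2=2,
#' S3=3, REM=4. The odd power keeps the sign: negative values mean the
#' model tends to overshoot toward later stage codes.
#'
#' @param true_labels,predicted_labels Equal-length canonical label vectors.
#' @return A single number (possibly negative).
#' @export
test_cost_index <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  codes <- stage_codes()
  y <- codes[as.character(as_stage_factor(true_labels))]
  h <- codes[as.character(as_stage_factor(predicted_labels))]
  mean((y - h)^3)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix with every summary statistic: overall
#' accuracy, per-stage F1 (the table layout used for staging results),
#' Cohen's kappa and the Test Cost Index.
#'
#' @param true_labels,predicted_labels Equal-length canonical label vectors.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(true_labels, predicted_labels) {
  cm <- confusion(true_labels, predicted_labels)
  bm <- basic_metrics(cm)
  structure(
    list(confusion = cm,
         n_epochs = sum(cm),
         accuracy = bm$accuracy,
         per_class = bm$per_class,
         macro_f1 = bm$macro_f1,
         macro_precision = bm$macro_precision,
         macro_recall = bm$macro_recall,
         kappa = cohen_kappa(cm),
         tci = test_cost_index(true_labels, predicted_labels)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$n_epochs, "epochs\n")
  cat(sprintf("  accuracy %.2f%%  kappa %.3f  TCI %.3f  macro-F1 %.2f%%\n",
              x$accuracy, x$kappa, x$tci, x$macro_f1))
  f1 <- sprintf("%.1f", x$per_class$f1)
  cat("  F1 per stage:", paste(x$per_class$class, f1, collapse = "  "), "\n")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the summary row (per-stage F1, accuracy, kappa, TCI) as CSV or
#' JSON, and optionally the confusion matrix as CSV.
#'
#' @param report An [eval_report()].
#' @param path Output path for the summary.
#' @param format `"csv"` or `"json"`.
#' @param confusion_path Optional CSV path for the confusion matrix.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, format = c("csv", "json"),
                              confusion_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  format <- match.arg(format)
  row <- c(list(n_epochs = report$n_epochs),
           stats::setNames(as.list(report$per_class$f1),
                           paste0("f1_", report$per_class$class)),
           list(accuracy = report$accuracy, kappa = report$kappa,
                tci = report$tci, macro_f1 = report$macro_f1))
  if (format == "csv") {
    utils::write.csv(as.data.frame(row), path, row.names = FALSE)
  } else {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(confusion_path)) {
    utils::write.csv(as.data.frame(unclass(report$confusion)), confusion_path)
  }
  invisible(path)
}
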