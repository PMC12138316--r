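#' Confusion matrix and threshold metrics
#'
#' Computes the 2x2 confusion matrix (rows = truth, columns = prediction,
#' class order 0 then 1) and accuracy, precision, recall, and F1 with the
#' fake class (label 1) as positive. Ratios with a zero denominator are
#' reported as `NA` together with a reason in `$undefined`, never silently
#' as 0.
#'
#' @param truth Integer vector of 0/1 true labels.
#' @param pred Integer vector of 0/1 predictions, same length.
#' @return Object of class `metrics_report`: list with `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1`, `n`, `positive_class`,
#'   `undefined` (named character vector of reasons, possibly empty).
#' @export
#' @examples
#' confusion_and_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_and_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length.",
          class = "fuzzrank_input_error")
  }
  if (length(truth) < 1) {
    abort("Need at least one observation.", class = "fuzzrank_input_error")
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  confusion <- table(factor(truth, levels = 0:1),
                     factor(pred, levels = 0:1))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(truth = c("0", "1"),
                                      pred = c("0", "1")))
  tp <- confusion["1", "1"]; tn <- confusion["0", "0"]
  fp <- confusion["0", "1"]; fn <- confusion["1", "0"]
  n <- length(truth)
  undefined <- character()
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp == 0) {
    undefined["precision"] <- "no positive predictions (TP + FP = 0)"
    NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    undefined["recall"] <- "no positive truths (TP + FN = 0)"
    NA_real_
  } else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) {
    undefined["f1"] <- "precision or recall undefined"
    NA_real_
  } else if (precision + recall == 0) {
    undefined["f1"] <- "precision + recall = 0"
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(confusion = confusion, accuracy = accuracy,
                 precision = precision, recall = recall, f1 = f1,
                 n = n, positive_class = 1L, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, "(positive class: fake)\n")
  print(x$confusion)
  cat(sprintf("  accuracy %.4f  precision %s  recall %s  f1 %s\n",
              x$accuracy, format(x$precision), format(x$recall),
              format(x$f1)))
  if (length(x$undefined) > 0) {
    cat("  undefined:", paste(names(x$undefined), x$undefined,
                              sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' AUC equals the probability that a random positive item outscores a random
#' negative one, with ties credited one half:
#' `(#\{score_pos > score_neg\} + 0.5 * #ties) / (n_pos * n_neg)`.
#' Computed via midranks, which is algebraically identical to the pairwise
#' enumeration.
#'
#' @param scores Numeric scores, higher = more likely positive (fake).
#' @param truth Integer 0/1 truth labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
roc_auc <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    abort("`scores` and `truth` must have equal length.",
          class = "fuzzrank_input_error")
  }
  truth <- as.integer(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined with a single-class truth vector.",
          class = "fuzzrank_undefined_auc_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Render a proportion as a percentage string
#'
#' @param x Numeric proportion in `[0, 1]` (or `NA`).
#' @param digits Decimal places (default 2).
#' @return Character, e.g. `"93.52"`; `NA` becomes `"N/A"`.
#' @export
render_percent <- function(x, digits = 2) {
  ifelse(is.na(x), "N/A", sprintf(paste0("%.", digits, "f"), 100 * x))
}

#' Parse a rendered percentage back to a proportion
#'
#' @param x Character vector from [render_percent()].
#' @return Numeric proportion; `"N/A"` becomes `NA`.
#' @export
parse_percent <- function(x) {
  ifelse(x == "N/A", NA_real_, as.numeric(x) / 100)
}

#' Side-by-side comparison of methods on one test set
#'
#' Builds the standard comparison table: one row per method with accuracy,
#' precision, recall, F1 and AUC as percentages (2 decimals). Methods
#' without continuous scores get `NA` AUC (rendered "N/A" on output). Rows
#' are sorted by method name so the table is independent of insertion order.
#'
#' @param methods Named list; each element a list with `pred` (0/1 vector)
#'   and optionally `scores` (numeric vector for AUC).
#' @param truth Integer 0/1 truth labels.
#' @return Tibble with columns `model`, `accuracy`, `precision`, `recall`,
#'   `f1`, `auc` (percent, rounded to 2 decimals; `auc` may be `NA`).
#' @export
comparison_report <- function(methods, truth) {
  if (length(methods) == 0 || is.null(names(methods))) {
    abort("`methods` must be a non-empty named list.",
          class = "fuzzrank_input_error")
  }
  rows <- purrr::imap(methods, function(m, name) {
    rep <- confusion_and_metrics(truth, m$pred)
    auc <- if (!is.null(m$scores)) roc_auc(m$scores, truth) else NA_real_
    tibble::tibble(model = name,
                   accuracy = round(100 * rep$accuracy, 2),
                   precision = round(100 * rep$precision, 2),
                   recall = round(100 * rep$recall, 2),
                   f1 = round(100 * rep$f1, 2),
                   auc = round(100 * auc, 2))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$model)
}

#' Write a comparison report to CSV and JSON
#'
#' @param report Tibble from [comparison_report()].
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return The report, invisibly.
#' @export
write_comparison_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  rendered <- dplyr::mutate(report, dplyr::across(
    c("accuracy", "precision", "recall", "f1", "auc"),
    ~ ifelse(is.na(.x), "N/A", sprintf("%.2f", .x))))
  if (!is.null(csv_path)) readr::write_csv(rendered, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(rendered, json_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(report)
}
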