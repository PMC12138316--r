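stratified_folds <- function(labels, folds, seed) {
  # per-class shuffling, then round-robin fold assignment
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Train a linear SVM with stratified k-fold cross-validation
#'
#' Fits a linear-kernel SVM on each training fold, evaluates on the held-out
#' fold, and returns the fold model with the highest validation F1 for the
#' positive class (fake, label 1) together with the full per-fold metric
#' table. Folding is stratified so both classes appear in every training
#' fold, and the whole procedure is deterministic under a fixed seed.
#'
#' @param features Numeric matrix or `dgCMatrix` of predictors (rows =
#'   documents), e.g. from [tfidf_transform()].
#' @param labels Integer vector of 0/1 labels.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param cost SVM regularization constant C (default 1, no class
#'   weighting).
#' @return List of class `svm_cv_fit`: `best_model` (an [e1071::svm] fit),
#'   `best_fold`, `fold_report` (tibble: fold, n_val, accuracy, precision,
#'   recall, f1), `cost`, `seed`.
#' @export
train_svm_cv <- function(features, labels, folds = 5L, seed = 1L, cost = 1.0) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present.",
          class = "fuzzrank_stratification_error")
  }
  assignment <- stratified_folds(labels, folds, seed)
  for (f in seq_len(folds)) {
    if (length(unique(labels[assignment != f])) < 2) {
      abort(sprintf("Fold %d leaves a single-class training set.", f),
            class = "fuzzrank_folding_error")
    }
  }
  fits <- vector("list", folds)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- assignment != f
    fit <- e1071::svm(x = features[tr, , drop = FALSE],
                      y = factor(labels[tr], levels = c(0, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    pred <- as.integer(as.character(
      predict(fit, features[!tr, , drop = FALSE])))
    m <- confusion_and_metrics(labels[!tr], pred)
    fits[[f]] <- fit
    rows[[f]] <- tibble::tibble(fold = f, n_val = sum(!tr),
                                accuracy = m$accuracy,
                                precision = m$precision,
                                recall = m$recall, f1 = m$f1)
  }
  report <- dplyr::bind_rows(rows)
  f1s <- ifelse(is.na(report$f1), -Inf, report$f1)
  best <- which.max(f1s)
  structure(list(best_model = fits[[best]], best_fold = best,
                 fold_report = report, cost = cost, seed = as.integer(seed)),
            class = "svm_cv_fit")
}

#' @export
print.svm_cv_fit <- function(x, ...) {
  cat("<svm_cv_fit> best fold:", x$best_fold, "(validation F1 =",
      sprintf("%.4f", x$fold_report$f1[x$best_fold]), ")\n")
  print(x$fold_report)
  invisible(x)
}

#' Predict binary labels with a cross-validated SVM fit
#'
#' @param object An `svm_cv_fit`.
#' @param features Feature matrix aligned with the training vocabulary.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.svm_cv_fit <- function(object, features, ...) {
  as.integer(as.character(predict(object$best_model, as.matrix(features))))
}
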