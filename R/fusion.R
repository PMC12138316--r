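#' Fusion configuration
#'
#' Settings for the Gompertz fuzzy-rank fusion: the scale constant of the
#' reparameterized Gompertz rank function and the tie-break rule applied when
#' two classes reach exactly the same fused score.
#'
#' @param gompertz_scale Positive scale constant `s` of the rank function
#'   `R(p) = 1 - exp(-exp(-s * p))`. Default 2: confidences in `[0, 1]` then
#'   span ranks from about 0.13 (certain) up to 0.63 (no confidence).
#' @param tie_break Tie-break rule at equal fused scores. Only
#'   `"lowest-class-index"` is implemented; it is deterministic.
#' @return An object of class `fusion_config`.
#' @export
#' @examples
#' fusion_config()
#' fusion_config(gompertz_scale = 1.5)
fusion_config <- function(gompertz_scale = 2.0, tie_break = "lowest-class-index") {
  if (!is.numeric(gompertz_scale) || length(gompertz_scale) != 1 ||
      !is.finite(gompertz_scale) || gompertz_scale <= 0) {
    abort("`gompertz_scale` must be a single positive number.",
          class = "fuzzrank_config_error")
  }
  tie_break <- match.arg(tie_break, "lowest-class-index")
  structure(list(gompertz_scale = gompertz_scale, tie_break = tie_break),
            class = "fusion_config")
}

#' Gompertz fuzzy rank of a confidence value
#'
#' Transforms a classifier confidence `p` into a fuzzy rank
#' `R(p) = 1 - exp(-exp(-s * p))` using the reparameterized Gompertz function.
#' `R` is strictly decreasing in `p`, so a higher confidence earns a better
#' (smaller) rank. Vectorized over `p`.
#'
#' @param p Numeric vector of confidences, each in `[0, 1]`.
#' @param config A [fusion_config()].
#' @return Numeric vector of ranks, each strictly inside `(0, 1)`.
#' @export
#' @examples
#' gompertz_fuzzy_rank(c(0, 0.5, 1))
gompertz_fuzzy_rank <- function(p, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1].", class = "fuzzrank_domain_error")
  }
  1 - exp(-exp(-config$gompertz_scale * p))
}

#' Construct and validate a classifier probability matrix
#'
#' A probability matrix holds one row per classifier and one column per class;
#' each row is that classifier's predicted distribution for a single item.
#' For the misinformation task there are two classes: column 1 is class 0
#' (genuine) and column 2 is class 1 (fake).
#'
#' @param values Numeric `K x C` matrix, `K >= 1` classifiers, `C >= 2`
#'   classes, entries in `[0, 1]`, rows summing to 1 within `tol`.
#' @param classifier_ids Optional character vector of `K` row labels.
#' @param class_ids Optional vector of `C` class labels; defaults to
#'   `0:(C-1)`.
#' @param renormalize If `TRUE`, rows whose sums deviate from 1 by more than
#'   `tol` but are positive are rescaled instead of rejected. Softmax outputs
#'   carry float noise; the default keeps validation strict.
#' @param tol Row-sum tolerance (default `1e-6`).
#' @return A matrix of class `probability_matrix` with classifier ids as row
#'   names and class ids as column names.
#' @export
#' @examples
#' probability_matrix(rbind(c(0.9, 0.1), c(0.4, 0.6)))
probability_matrix <- function(values, classifier_ids = NULL, class_ids = NULL,
                               renormalize = FALSE, tol = 1e-6) {
  if (is.null(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "fuzzrank_input_error")
  }
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 2) {
    abort("A probability matrix needs K >= 1 classifiers and C >= 2 classes.",
          class = "fuzzrank_input_error")
  }
  if (anyNA(values) || any(values < 0 | values > 1)) {
    abort("All confidences must lie in [0, 1].",
          class = "fuzzrank_validation_error")
  }
  sums <- rowSums(values)
  off <- which(abs(sums - 1) > tol)
  if (length(off) > 0) {
    if (renormalize && all(sums[off] > 0)) {
      values[off, ] <- values[off, , drop = FALSE] / sums[off]
    } else {
      abort(sprintf("Row %d sums to %.8f, not 1 (tolerance %g).",
                    off[1], sums[off[1]], tol),
            class = "fuzzrank_validation_error")
    }
  }
  K <- nrow(values); C <- ncol(values)
  if (is.null(classifier_ids)) {
    classifier_ids <- rownames(values) %||% paste0("clf", seq_len(K))
  }
  if (is.null(class_ids)) {
    class_ids <- colnames(values) %||% as.character(0:(C - 1))
  }
  stopifnot(length(classifier_ids) == K, length(class_ids) == C)
  dimnames(values) <- list(classifier_ids, as.character(class_ids))
  class(values) <- c("probability_matrix", "matrix")
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_probability_matrix <- function(x, ...) {
  if (inherits(x, "probability_matrix")) x else probability_matrix(x, ...)
}

#' Fuse classifier confidences with Gompertz fuzzy ranks
#'
#' Computes each classifier's fuzzy rank for each class, sums ranks per class
#' (`RS`), weights by the complement confidence factor
#' `CCF[c] = 1 - mean_k p[k, c]` (low when the ensemble collectively backs
#' class `c`), and picks the class with the minimal fused score
#' `FS[c] = RS[c] * CCF[c]`. Per-case weighting is implicit in the rank / CCF
#' arithmetic; no fixed classifier weights are learned.
#'
#' For two classes a probability-like score for the positive (fake) class is
#' also returned: `roc_score = FS[1] / (FS[1] + FS[2])` over the class-0 and
#' class-1 fused scores — monotone in the evidence for "fake", bounded in
#' `[0, 1]`, and 0.5 under symmetry (defined as 0.5 when both scores are 0).
#'
#' @param probs A [probability_matrix()] (or plain matrix coerced to one).
#' @param config A [fusion_config()].
#' @param renormalize Passed to [probability_matrix()] when `probs` is a plain
#'   matrix.
#' @return An object of class `fusion_result`: list with `rank_matrix`
#'   (`K x C` ranks), `rank_sum`, `ccf`, `fused_score` (all length-`C`),
#'   `decision` (a class id), `decision_index` (column index), and
#'   `roc_score` (`NA` unless `C == 2`).
#' @export
#' @examples
#' pm <- probability_matrix(rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6)))
#' fuzzy_fuse(pm)
fuzzy_fuse <- function(probs, config = fusion_config(), renormalize = FALSE) {
  probs <- as_probability_matrix(probs, renormalize = renormalize)
  stopifnot(inherits(config, "fusion_config"))
  K <- nrow(probs); C <- ncol(probs)
  rank_matrix <- gompertz_fuzzy_rank(as.numeric(probs), config)
  dim(rank_matrix) <- dim(probs)
  dimnames(rank_matrix) <- dimnames(probs)
  rank_sum <- colSums(rank_matrix)
  ccf <- 1 - colMeans(unclass(probs))
  fused_score <- rank_sum * ccf
  # lowest-class-index tie-break: which.min already keeps the first minimum
  decision_index <- which.min(fused_score)
  class_ids <- colnames(probs)
  roc_score <- NA_real_
  if (C == 2) {
    denom <- fused_score[1] + fused_score[2]
    roc_score <- if (denom == 0) 0.5 else unname(fused_score[1] / denom)
  }
  structure(
    list(rank_matrix = rank_matrix,
         rank_sum = rank_sum,
         ccf = ccf,
         fused_score = fused_score,
         decision = class_ids[decision_index],
         decision_index = decision_index,
         roc_score = roc_score,
         class_ids = class_ids),
    class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>", nrow(x$rank_matrix), "classifiers,",
      length(x$class_ids), "classes\n")
  cat("  fused scores:",
      paste(sprintf("%s=%.6f", x$class_ids, x$fused_score), collapse = ", "),
      "\n")
  cat("  decision:", x$decision)
  if (!is.na(x$roc_score)) cat("  (score for fake:", sprintf("%.4f", x$roc_score), ")")
  cat("\n")
  invisible(x)
}

#' Soft (weighted) voting baseline
#'
#' Averages the classifiers' probability vectors, optionally with nonnegative
#' weights (renormalized internally), and takes the argmax; ties go to the
#' lowest class index.
#'
#' @param probs A [probability_matrix()] or plain matrix.
#' @param weights Optional numeric vector of `K` nonnegative weights with a
#'   positive sum.
#' @return An object of class `soft_vote_result`: list with `averaged`
#'   (length-`C` distribution), `decision`, `decision_index`, and `roc_score`
#'   (the averaged probability of class 1 when `C == 2`).
#' @export
#' @examples
#' soft_vote(rbind(c(0.6, 0.4), c(0.2, 0.8)))
soft_vote <- function(probs, weights = NULL) {
  probs <- as_probability_matrix(probs)
  K <- nrow(probs); C <- ncol(probs)
  if (is.null(weights)) {
    weights <- rep(1 / K, K)
  } else {
    if (!is.numeric(weights) || length(weights) != K || any(weights < 0)) {
      abort("`weights` must be K nonnegative numbers.",
            class = "fuzzrank_config_error")
    }
    s <- sum(weights)
    if (s <= 0) abort("`weights` must sum to a positive value.",
                      class = "fuzzrank_config_error")
    weights <- weights / s
  }
  averaged <- as.numeric(crossprod(unclass(probs), weights))
  names(averaged) <- colnames(probs)
  decision_index <- which.max(averaged)
  structure(
    list(averaged = averaged,
         decision = colnames(probs)[decision_index],
         decision_index = decision_index,
         roc_score = if (C == 2) unname(averaged[2]) else NA_real_,
         class_ids = colnames(probs)),
    class = "soft_vote_result")
}

#' @export
print.soft_vote_result <- function(x, ...) {
  cat("<soft_vote_result> averaged:",
      paste(sprintf("%s=%.4f", x$class_ids, x$averaged), collapse = ", "),
      " decision:", x$decision, "\n")
  invisible(x)
}

#' Extract ROC scores from fusion results
#'
#' Returns each two-class fusion result's probability-like score for the
#' positive (fake) class, suitable for [roc_auc()].
#'
#' @param results A list of `fusion_result` (or `soft_vote_result`) objects.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
fusion_auc_score <- function(results) {
  if (inherits(results, c("fusion_result", "soft_vote_result"))) {
    results <- list(results)
  }
  vapply(results, function(r) {
    if (length(r$class_ids) != 2) {
      abort("ROC scores are only defined for two-class results.",
            class = "fuzzrank_unsupported_error")
    }
    r$roc_score
  }, numeric(1))
}

#' Fuse a collection of per-item probability matrices
#'
#' Applies fuzzy rank fusion or (weighted) soft voting to every item of an
#' ensemble output and returns a tidy summary, one row per item.
#'
#' @param prob_list A list of probability matrices (one per item), e.g. from
#'   [gen_ensemble_outputs()] or [read_probability_matrices()].
#' @param method `"fuzzy"`, `"soft"`, or `"weighted"`.
#' @param config A [fusion_config()] (fuzzy method).
#' @param weights Classifier weights (weighted method).
#' @return A tibble with columns `item`, `decision`, `roc_score`, plus the
#'   per-class fused scores (fuzzy) or averaged probabilities (soft).
#' @export
fuse_ensemble <- function(prob_list, method = c("fuzzy", "soft", "weighted"),
                          config = fusion_config(), weights = NULL) {
  method <- match.arg(method)
  if (length(prob_list) == 0) {
    abort("`prob_list` is empty.", class = "fuzzrank_input_error")
  }
  items <- names(prob_list) %||% as.character(seq_along(prob_list))
  rows <- purrr::map2(prob_list, items, function(pm, id) {
    if (method == "fuzzy") {
      r <- fuzzy_fuse(pm, config)
      scores <- setNames(as.list(r$fused_score),
                         paste0("fused_", r$class_ids))
    } else {
      r <- soft_vote(pm, weights = if (method == "weighted") weights else NULL)
      scores <- setNames(as.list(r$averaged), paste0("avg_", r$class_ids))
    }
    tibble::tibble(item = id, decision = r$decision,
                   roc_score = r$roc_score, !!!scores)
  })
  dplyr::bind_rows(rows)
}
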