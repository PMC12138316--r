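#' Unigram tokenizer
#'
#' Lowercases, splits on runs of non-alphanumeric characters, and keeps
#' tokens of length >= 2.
#'
#' @param texts Character vector.
#' @return List of character vectors, one per text.
#' @export
tokenize_unigrams <- function(texts) {
  toks <- stringr::str_split(stringr::str_to_lower(texts), "[^a-z0-9]+")
  purrr::map(toks, ~ .x[nchar(.x) >= 2])
}

#' Fit a unigram TF-IDF model on training texts
#'
#' The vocabulary and document frequencies come from the training set only.
#' Inverse document frequency uses the smoothed formula
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, so every weight is >= 1 and a
#' term present in every document still contributes. Transformed rows are
#' L2-normalized.
#'
#' @param train_texts Non-empty character vector of training documents.
#' @return An object of class `tfidf_model` with elements `vocabulary`
#'   (token -> column index), `idf`, and `n_docs`.
#' @export
#' @examples
#' m <- fit_tfidf(c("a1 b1", "a1 c1"))
#' m$idf
fit_tfidf <- function(train_texts) {
  if (length(train_texts) == 0) {
    abort("Cannot fit TF-IDF on an empty corpus.",
          class = "fuzzrank_input_error")
  }
  toks <- tokenize_unigrams(train_texts)
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) {
    abort("No tokens of length >= 2 in the training corpus.",
          class = "fuzzrank_input_error")
  }
  n <- length(train_texts)
  df <- table(factor(unlist(purrr::map(toks, unique)), levels = vocab))
  idf <- log((1 + n) / (1 + as.numeric(df))) + 1
  names(idf) <- vocab
  structure(list(vocabulary = setNames(seq_along(vocab), vocab),
                 idf = idf, n_docs = n),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model>", length(x$vocabulary), "unigrams fit on", x$n_docs,
      "documents\n")
  invisible(x)
}

#' Transform texts into L2-normalized TF-IDF features
#'
#' Term frequency is the raw count; out-of-vocabulary tokens are ignored
#' (texts with only unseen tokens become all-zero rows and stay un-normalized).
#'
#' @param model A [fit_tfidf()] model.
#' @param texts Character vector to transform.
#' @return A sparse `dgCMatrix` of dimension `length(texts)` x vocabulary
#'   size.
#' @export
tfidf_transform <- function(model, texts) {
  stopifnot(inherits(model, "tfidf_model"))
  toks <- tokenize_unigrams(texts)
  triplets <- purrr::imap(toks, function(tk, i) {
    tk <- tk[tk %in% names(model$vocabulary)]
    if (length(tk) == 0) return(NULL)
    tf <- table(tk)
    j <- model$vocabulary[names(tf)]
    list(i = rep(i, length(j)), j = unname(j),
         x = as.numeric(tf) * model$idf[names(tf)])
  })
  triplets <- purrr::compact(triplets)
  if (length(triplets) == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(texts),
                                         length(model$vocabulary)),
                                dimnames = list(NULL,
                                                names(model$vocabulary))))
  }
  m <- Matrix::sparseMatrix(
    i = unlist(purrr::map(triplets, "i")),
    j = unlist(purrr::map(triplets, "j")),
    x = unname(unlist(purrr::map(triplets, "x"))),
    dims = c(length(texts), length(model$vocabulary)),
    dimnames = list(NULL, names(model$vocabulary)))
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% m
}

#' Convenience: fit on training texts and transform both sets
#'
#' @param train_texts Training documents (vocabulary source).
#' @param apply_texts Documents to transform with the fitted model; defaults
#'   to `train_texts`.
#' @return List with `model`, `train` (features), `apply` (features).
#' @export
tfidf_features <- function(train_texts, apply_texts = train_texts) {
  model <- fit_tfidf(train_texts)
  list(model = model,
       train = tfidf_transform(model, train_texts),
       apply = tfidf_transform(model, apply_texts))
}
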