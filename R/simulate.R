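filler_vocabulary <- function() {
  # neutral tokens, screened so no topic keyword occurs as a substring of a
  # token or across a token boundary ("post"/"covid" deliberately absent):
  # keyword presence in generated text is then fully generator-controlled
  c("report", "study", "data", "health", "people", "update", "news",
    "daily", "city", "group", "online", "share", "public", "claim",
    "press", "media", "week", "month", "state", "local", "video", "photo",
    "story", "event", "topic", "note", "item", "page", "number", "office",
    "school", "market", "travel", "doctor", "clinic", "survey", "record",
    "policy", "review", "notice")
}

#' Default class-conditional keyword prevalences
#'
#' Per-keyword probabilities that a fake / genuine text contains the
#' keyword. "immune" dominates fake texts while barely appearing in genuine
#' ones; "recovery" leans genuine but is present in a similar share of fake
#' texts; "variant", "complications", and "chronic" lean fake; the remaining
#' terms are low-prevalence background.
#'
#' @return Tibble with columns `keyword`, `fake`, `genuine`.
#' @export
default_keyword_prevalence <- function() {
  tibble::tribble(
    ~keyword,        ~fake, ~genuine,
    "chronic",        0.20,  0.10,
    "long-term",      0.15,  0.12,
    "persistent",     0.10,  0.08,
    "after-effects",  0.05,  0.03,
    "sequelae",       0.04,  0.05,
    "complications",  0.20,  0.08,
    "recovery",       0.25,  0.30,
    "post covid",     0.10,  0.08,
    "post-covid",     0.10,  0.08,
    "omicron",        0.15,  0.10,
    "subvariant",     0.08,  0.05,
    "reinfection",    0.12,  0.10,
    "immune",         0.55,  0.05,
    "variant",        0.30,  0.10)
}

#' Synthetic corpus generator configuration
#'
#' Defaults emulate the study corpus: 2361 fake and 566 genuine records
#' (2927 total), class-dependent keyword prevalence, and social-media noise
#' (URLs, emoji, near-duplicate posts).
#'
#' @param n_fake,n_genuine Class sizes (defaults 2361 / 566).
#' @param keyword_prevalence Tibble with columns `keyword`, `fake`,
#'   `genuine` of per-class inclusion probabilities; defaults to
#'   [default_keyword_prevalence()].
#' @param duplicate_rate Fraction of records planted as normalized-text
#'   duplicates of another same-class record (default 0.05).
#' @param url_emoji_rate Probability that a record carries a URL, and
#'   independently an emoji (default 0.3).
#' @param seed Integer seed; the corpus is byte-identical per seed.
#' @return Object of class `corpus_gen_config`.
#' @export
corpus_gen_config <- function(n_fake = 2361L, n_genuine = 566L,
                              keyword_prevalence = default_keyword_prevalence(),
                              duplicate_rate = 0.05, url_emoji_rate = 0.3,
                              seed = 7L) {
  kp <- tibble::as_tibble(keyword_prevalence)
  stopifnot(all(c("keyword", "fake", "genuine") %in% names(kp)))
  if (n_fake < 0 || n_genuine < 0 || n_fake + n_genuine == 0) {
    abort("Class sizes must be nonnegative with a positive total.",
          class = "fuzzrank_config_error")
  }
  probs <- c(kp$fake, kp$genuine, duplicate_rate, url_emoji_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("All rates and prevalences must lie in [0, 1].",
          class = "fuzzrank_config_error")
  }
  structure(list(n_fake = as.integer(n_fake),
                 n_genuine = as.integer(n_genuine),
                 keyword_prevalence = kp,
                 duplicate_rate = duplicate_rate,
                 url_emoji_rate = url_emoji_rate,
                 seed = as.integer(seed)),
            class = "corpus_gen_config")
}

random_url <- function(n) {
  paste0("https://t.co/", vapply(seq_len(n), function(i) {
    paste(sample(c(letters, 0:9), 8, replace = TRUE), collapse = "")
  }, character(1)))
}

#' Generate a labeled synthetic corpus with ground-truth bookkeeping
#'
#' Texts are assembled from a fixed neutral filler vocabulary plus
#' class-conditionally planted topic keywords; duplicates (case/whitespace
#' perturbed copies of a same-class record), URLs, and emoji are planted at
#' the configured rates. Every planted feature is recorded so recovery can
#' be checked against ground truth. Base (non-duplicate) texts are
#' guaranteed pairwise distinct, so the planted duplicate count equals the
#' number of records [deduplicate()] removes after cleaning.
#'
#' @param config A [corpus_gen_config()].
#' @return List with `records` (tibble: id, text, source, raw_label, label,
#'   cleaned) and `truth` (list: `keyword_flags` logical matrix,
#'   `is_duplicate`, `duplicate_of`, `has_url`, `has_emoji`,
#'   `n_duplicates`, `n_fake`, `n_genuine`).
#' @export
#' @examples
#' g <- gen_corpus(corpus_gen_config(n_fake = 40, n_genuine = 10, seed = 1))
#' nrow(g$records)
gen_corpus <- function(config = corpus_gen_config()) {
  stopifnot(inherits(config, "corpus_gen_config"))
  n <- config$n_fake + config$n_genuine
  kp <- config$keyword_prevalence
  n_kw <- nrow(kp)
  fillers <- filler_vocabulary()

  withr::with_seed(config$seed, {
    label <- sample(c(rep(1L, config$n_fake), rep(0L, config$n_genuine)))
    # class-conditional keyword inclusion
    flags <- matrix(FALSE, n, n_kw, dimnames = list(NULL, kp$keyword))
    for (j in seq_len(n_kw)) {
      p <- ifelse(label == 1L, kp$fake[j], kp$genuine[j])
      flags[, j] <- runif(n) < p
    }
    assemble <- function(i) {
      toks <- sample(fillers, sample(8:20, 1), replace = TRUE)
      kws <- kp$keyword[flags[i, ]]
      for (kw in kws) {
        pos <- sample(0:length(toks), 1)
        toks <- append(toks, kw, after = pos)
      }
      paste(toks, collapse = " ")
    }
    text <- vapply(seq_len(n), assemble, character(1))
    # base texts must be pairwise distinct under dedup normalization
    repeat {
      dup <- duplicated(normalize_text(text))
      if (!any(dup)) break
      text[dup] <- vapply(which(dup), assemble, character(1))
    }

    n_dup <- round(config$duplicate_rate * n)
    is_duplicate <- rep(FALSE, n)
    duplicate_of <- rep(NA_character_, n)
    ids <- sprintf("syn%05d", seq_len(n))
    if (n_dup > 0) {
      dup_idx <- sample(n, n_dup)
      is_duplicate[dup_idx] <- TRUE
      for (i in dup_idx) {
        pool <- which(!is_duplicate & label == label[i] & seq_len(n) != i)
        if (length(pool) == 0) {
          abort("Not enough unique records to plant duplicates.",
                class = "fuzzrank_config_error")
        }
        src <- if (length(pool) == 1) pool else sample(pool, 1)
        # copy text with case/whitespace perturbation: raw strings differ,
        # normalized strings match
        perturbed <- paste0(stringr::str_to_upper(substr(text[src], 1, 1)),
                            substr(text[src], 2, nchar(text[src])), "  ")
        text[i] <- perturbed
        flags[i, ] <- flags[src, ]
        duplicate_of[i] <- ids[src]
      }
    }

    has_url <- runif(n) < config$url_emoji_rate
    has_emoji <- runif(n) < config$url_emoji_rate
    text[has_url] <- paste(text[has_url], random_url(sum(has_url)))
    emojis <- c("\U0001F637", "\U0001F489", "\U0001F9A0", "\U0001F614")
    text[has_emoji] <- paste(text[has_emoji],
                             sample(emojis, sum(has_emoji), replace = TRUE))
  })

  records <- tibble::tibble(
    id = ids, text = text, source = "synthetic",
    raw_label = ifelse(label == 1L, "fake", "genuine"),
    label = label, cleaned = FALSE)
  list(records = records,
       truth = list(keyword_flags = flags,
                    is_duplicate = is_duplicate,
                    duplicate_of = duplicate_of,
                    has_url = has_url,
                    has_emoji = has_emoji,
                    n_duplicates = sum(is_duplicate),
                    n_fake = config$n_fake,
                    n_genuine = config$n_genuine))
}

#' Correlated ensemble output generator configuration
#'
#' Emulates the test-time outputs of several fine-tuned classifiers of a
#' two-class task: per item, a shared latent uniform couples the
#' classifiers' correctness (tunable error correlation), and the confidence
#' assigned to the predicted class is Beta-distributed, rescaled to
#' `[0.5, 1]` so the predicted class is always the row argmax.
#'
#' @param n_items Number of test items (default 1000).
#' @param accuracies Per-classifier marginal accuracy targets in (0, 1);
#'   default `c(0.9, 0.8, 0.7)` (also fixes K).
#' @param correlation Probability a classifier reuses the shared latent
#'   rather than an independent one, in `[0, 1]` (default 0.3).
#' @param confidence_concentration Two Beta shape parameters of the
#'   confidence draw (default `c(5, 2)`: confidently-peaked but noisy).
#' @param class_prior P(item is fake), default 0.8 — close to the fake share
#'   of the emulated corpus.
#' @param seed Integer seed.
#' @return Object of class `ensemble_gen_config`.
#' @export
ensemble_gen_config <- function(n_items = 1000L,
                                accuracies = c(0.9, 0.8, 0.7),
                                correlation = 0.3,
                                confidence_concentration = c(5, 2),
                                class_prior = 0.8, seed = 7L) {
  if (length(accuracies) == 0) {
    abort("Need at least one classifier (K >= 1).",
          class = "fuzzrank_config_error")
  }
  if (any(accuracies <= 0 | accuracies >= 1)) {
    abort("Accuracies must lie strictly in (0, 1).",
          class = "fuzzrank_config_error")
  }
  if (correlation < 0 || correlation > 1) {
    abort("`correlation` must lie in [0, 1].",
          class = "fuzzrank_config_error")
  }
  if (class_prior <= 0 || class_prior >= 1) {
    abort("`class_prior` must lie strictly in (0, 1).",
          class = "fuzzrank_config_error")
  }
  stopifnot(length(confidence_concentration) == 2,
            all(confidence_concentration > 0))
  structure(list(n_items = as.integer(n_items), accuracies = accuracies,
                 K = length(accuracies), correlation = correlation,
                 confidence_concentration = confidence_concentration,
                 class_prior = class_prior, seed = as.integer(seed)),
            class = "ensemble_gen_config")
}

#' Generate correlated multi-classifier probability outputs
#'
#' Per item `i`: truth ~ Bernoulli(class_prior); a shared latent uniform
#' `u_i` drives correctness — classifier `k` is correct when `v_ik <
#' accuracies[k]`, where `v_ik = u_i` with probability `correlation` and an
#' independent uniform otherwise. The predicted class receives confidence
#' `0.5 + 0.5 * Beta(a, b)`; the other class gets the complement, so each
#' row is a valid distribution with the predicted class as argmax.
#'
#' @param config An [ensemble_gen_config()].
#' @return List with `truth` (integer 0/1 vector), `probs` (named list of
#'   `K x 2` [probability_matrix()] objects), and `correct` (`n x K` logical
#'   matrix of planted per-classifier correctness).
#' @export
#' @examples
#' out <- gen_ensemble_outputs(ensemble_gen_config(n_items = 5, seed = 1))
#' out$probs[[1]]
gen_ensemble_outputs <- function(config = ensemble_gen_config()) {
  stopifnot(inherits(config, "ensemble_gen_config"))
  n <- config$n_items; K <- config$K
  a <- config$confidence_concentration[1]
  b <- config$confidence_concentration[2]
  withr::with_seed(config$seed, {
    truth <- rbinom(n, 1, config$class_prior)
    u <- runif(n)
    correct <- matrix(FALSE, n, K)
    conf <- matrix(NA_real_, n, K)
    for (k in seq_len(K)) {
      shared <- runif(n) < config$correlation
      v <- ifelse(shared, u, runif(n))
      correct[, k] <- v < config$accuracies[k]
      conf[, k] <- 0.5 + 0.5 * rbeta(n, a, b)
    }
  })
  clf_ids <- paste0("clf", seq_len(K))
  probs <- lapply(seq_len(n), function(i) {
    pred <- ifelse(correct[i, ], truth[i], 1L - truth[i])
    p1 <- ifelse(pred == 1L, conf[i, ], 1 - conf[i, ])
    probability_matrix(cbind(1 - p1, p1), classifier_ids = clf_ids,
                       class_ids = c("0", "1"))
  })
  names(probs) <- paste0("item", seq_len(n))
  list(truth = truth, probs = probs, correct = correct)
}
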