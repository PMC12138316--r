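#' Topic keywords for long COVID and reinfection
#'
#' The default keyword list used to filter a corpus down to texts about the
#' extended impacts of COVID-19 (long COVID, reinfection). Matching is
#' case-insensitive substring matching, so the hyphenated and two-word
#' spellings are listed separately.
#'
#' @return Character vector of 14 keywords.
#' @export
covid_keywords <- function() {
  c("chronic", "long-term", "persistent", "after-effects", "sequelae",
    "complications", "recovery", "post covid", "post-covid", "omicron",
    "subvariant", "reinfection", "immune", "variant")
}

#' Default source-label harmonization map
#'
#' Maps each source's native label vocabulary onto the binary scheme
#' 0 = genuine, 1 = fake. Fact-check verdict scales are collapsed:
#' PolitiFact's six-point scale keeps only "true" and "mostly true" as
#' genuine; Snopes keeps "true", "mostly true", and "correct-attribution" as
#' genuine and treats its other 11 verdicts (mixtures, satire, scams,
#' legends, ...) as fake. Sources that already ship binary labels use the
#' generic genuine/fake vocabulary. The map is plain data so any published
#' reclassification can be swapped in via [read_label_map()].
#'
#' @return Named list: source -> named integer vector (raw label -> 0/1).
#' @export
default_label_map <- function() {
  politifact <- c("true" = 0L, "mostly true" = 0L,
                  "half-true" = 1L, "barely true" = 1L,
                  "false" = 1L, "pants-on-fire" = 1L)
  snopes <- c("true" = 0L, "mostly true" = 0L, "correct-attribution" = 0L,
              "mixture" = 1L, "mostly false" = 1L, "false" = 1L,
              "unproven" = 1L, "outdated" = 1L, "miscaptioned" = 1L,
              "misattributed" = 1L, "scam" = 1L, "legend" = 1L,
              "labeled-satire" = 1L, "lost-legend" = 1L)
  binary <- c("genuine" = 0L, "real" = 0L, "fake" = 1L)
  list(PolitiFact = politifact,
       Snopes = snopes,
       CTF = binary,
       FightingInfodemic = binary,
       CoAID = binary,
       FibVID = binary,
       FaCOV = binary,
       CDC_WHO = c("genuine" = 0L),
       synthetic = binary)
}

#' Read a label map from JSON
#'
#' @param path JSON file: object of objects, source -> raw label -> 0/1.
#' @return Named list usable as `label_map` in [harmonize_labels()].
#' @export
read_label_map <- function(path) {
  raw <- jsonlite::read_json(path)
  purrr::map(raw, ~ unlist(.x))
}

# Unicode blocks covering standard emoji (pictographs, emoticons, transport,
# flags, dingbats, misc symbols) plus variation selector and ZWJ.
emoji_pattern <- paste0(
  "[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}",
  "\\x{2190}-\\x{21FF}\\x{2300}-\\x{23FF}\\x{1F1E6}-\\x{1F1FF}",
  "\\x{FE0F}\\x{200D}]")

url_pattern <- "(?i)\\b(?:https?://|www\\.)\\S+"

#' Clean text: strip URLs and emoji, normalize whitespace
#'
#' Removes URL substrings (`http://`, `https://`, `www.` forms) and emoji
#' code points (standard emoji Unicode blocks), collapses whitespace runs to
#' single spaces, and trims. Idempotent; an empty result is allowed (and
#' flagged downstream by [clean_corpus()]).
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' clean_text("Long COVID is real https://t.co/abc \U0001F637")
clean_text <- function(text) {
  out <- stringr::str_remove_all(text, url_pattern)
  out <- stringr::str_remove_all(out, emoji_pattern)
  out <- stringr::str_replace_all(out, "\\s+", " ")
  stringr::str_trim(out)
}

#' Clean every record of a corpus
#'
#' Applies [clean_text()] to the `text` column, marks records `cleaned`, and
#' warns about records whose text became empty (they are retained and
#' flagged, not silently dropped).
#'
#' @param records Tibble with at least `id` and `text` columns.
#' @return The tibble with cleaned `text`, `cleaned = TRUE`, and a logical
#'   `empty_after_cleaning` column.
#' @export
clean_corpus <- function(records) {
  records <- tibble::as_tibble(records)
  records$text <- clean_text(records$text)
  records$cleaned <- TRUE
  records$empty_after_cleaning <- !nzchar(records$text)
  if (any(records$empty_after_cleaning)) {
    warn(sprintf("%d record(s) are empty after cleaning.",
                 sum(records$empty_after_cleaning)))
  }
  records
}

normalize_text <- function(text) {
  stringr::str_trim(stringr::str_replace_all(stringr::str_to_lower(text),
                                             "\\s+", " "))
}

#' Remove duplicate records
#'
#' Duplicates are exact matches on normalized text (case-folded, whitespace
#' collapsed); the first occurrence is retained and order is stable. The
#' number of removed records is attached as attribute `n_removed`.
#'
#' @param records Tibble with a `text` column.
#' @return The deduplicated tibble, with `attr(, "n_removed")`.
#' @export
deduplicate <- function(records) {
  records <- tibble::as_tibble(records)
  keep <- !duplicated(normalize_text(records$text))
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Filter records by topic keywords
#'
#' Retains records whose normalized text contains at least one keyword as a
#' case-insensitive substring; order is preserved.
#'
#' @param records Tibble with a `text` column.
#' @param keywords Non-empty character vector; defaults to [covid_keywords()].
#' @return The filtered tibble.
#' @export
keyword_filter <- function(records, keywords = covid_keywords()) {
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    abort("`keywords` must be a non-empty character vector.",
          class = "fuzzrank_config_error")
  }
  records <- tibble::as_tibble(records)
  txt <- normalize_text(records$text)
  hit <- rep(FALSE, length(txt))
  for (kw in stringr::str_to_lower(keywords)) {
    hit <- hit | stringr::str_detect(txt, stringr::fixed(kw))
  }
  records[hit, , drop = FALSE]
}

#' Harmonize one source label to the binary scheme
#'
#' @param source Source name (must be a key of `label_map`).
#' @param raw_label Raw label string in the source's vocabulary.
#' @param label_map Named list, source -> named vector of 0/1; defaults to
#'   [default_label_map()].
#' @return Integer 0 (genuine) or 1 (fake).
#' @export
#' @examples
#' harmonize_label("PolitiFact", "mostly true")
harmonize_label <- function(source, raw_label, label_map = default_label_map()) {
  if (!source %in% names(label_map)) {
    abort(sprintf("No label map for source '%s'.", source),
          class = "fuzzrank_mapping_error")
  }
  m <- label_map[[source]]
  key <- stringr::str_to_lower(stringr::str_trim(raw_label))
  if (!key %in% names(m)) {
    abort(sprintf("Unmapped label '%s' for source '%s'.", raw_label, source),
          class = "fuzzrank_mapping_error")
  }
  as.integer(m[[key]])
}

#' Harmonize all labels of a corpus
#'
#' Encodes every record's raw label as 0 (genuine) / 1 (fake). Unknown
#' labels raise an error naming the source and label; records are never
#' silently dropped.
#'
#' @inheritParams harmonize_label
#' @param records Tibble with `source` and `raw_label` columns.
#' @return The tibble with an integer `label` column.
#' @export
harmonize_labels <- function(records, label_map = default_label_map()) {
  records <- tibble::as_tibble(records)
  records$label <- purrr::map2_int(records$source, records$raw_label,
                                   harmonize_label, label_map = label_map)
  records
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Splits records so each partition preserves the class proportions of the
#' whole — essential here because the corpus is heavily imbalanced toward
#' fake samples, and random sampling could starve the test set of genuine
#' texts. The total test size is `round_half_up(test_fraction * N)`; per-class
#' counts come from largest-remainder apportionment so they sum exactly to
#' the total. The same seed always yields a bit-identical split.
#'
#' @param records Tibble with `id` and encoded `label` columns; both classes
#'   must be present.
#' @param test_fraction Test share in (0, 1); default 0.1.
#' @param seed Integer seed.
#' @return An object of class `split_indices`: list with `train_ids`,
#'   `test_ids`, `seed`, `test_fraction`.
#' @export
stratified_split <- function(records, test_fraction = 0.1, seed = 1L) {
  records <- tibble::as_tibble(records)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.",
          class = "fuzzrank_config_error")
  }
  if (anyNA(records$label)) {
    abort("All records must carry an encoded label before splitting.",
          class = "fuzzrank_input_error")
  }
  classes <- sort(unique(records$label))
  if (length(classes) < 2) {
    abort("Both classes must be present to stratify.",
          class = "fuzzrank_stratification_error")
  }
  n <- nrow(records)
  n_test <- round_half_up(test_fraction * n)
  quota <- vapply(classes, function(cl) test_fraction * sum(records$label == cl),
                  numeric(1))
  base <- floor(quota)
  remainder <- quota - base
  short <- n_test - sum(base)
  # largest remainders get the leftover seats; ties by class order
  if (short > 0) {
    top <- order(remainder, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  } else if (short < 0) {
    bottom <- order(remainder, decreasing = FALSE)[seq_len(-short)]
    base[bottom] <- base[bottom] - 1
  }
  if (any(base < 1)) {
    abort("A class has fewer than one test candidate; cannot stratify.",
          class = "fuzzrank_stratification_error")
  }
  test_ids <- withr::with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      ids <- records$id[records$label == classes[i]]
      sample(ids, base[i])
    }), use.names = FALSE)
  })
  structure(
    list(train_ids = setdiff(records$id, test_ids),
         test_ids = test_ids,
         seed = as.integer(seed),
         test_fraction = test_fraction),
    class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat("<split_indices>", length(x$train_ids), "train /", length(x$test_ids),
      "test (fraction", x$test_fraction, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Per-source corpus ledger
#'
#' Counts fake and genuine records per source, plus a totals row whose
#' entries equal the column sums. Row invariant:
#' `sample_size = fake_count + genuine_count`.
#'
#' @param records Tibble with `source` and encoded `label` columns; an empty
#'   tibble yields an all-zero totals-only ledger.
#' @return A tibble with columns `source`, `sample_size`, `fake_count`,
#'   `genuine_count`; the last row is `Total`.
#' @export
ledger_summary <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(source = "Total", sample_size = 0L,
                          fake_count = 0L, genuine_count = 0L))
  }
  if (anyNA(records$label)) {
    abort("All records must carry an encoded label.",
          class = "fuzzrank_input_error")
  }
  rows <- records |>
    dplyr::group_by(source = as.character(.data$source)) |>
    dplyr::summarise(sample_size = dplyr::n(),
                     fake_count = sum(.data$label == 1L),
                     genuine_count = sum(.data$label == 0L),
                     .groups = "drop")
  totals <- tibble::tibble(source = "Total",
                           sample_size = sum(rows$sample_size),
                           fake_count = sum(rows$fake_count),
                           genuine_count = sum(rows$genuine_count))
  dplyr::bind_rows(rows, totals)
}

#' Build a ledger from per-source counts
#'
#' Takes an already-aggregated per-source count table (e.g. the published
#' sample-size table of a collected corpus), validates that each row's
#' sample size equals its fake + genuine counts, and appends a computed
#' totals row.
#'
#' @param counts Tibble/data frame with columns `source`, `sample_size`,
#'   `fake_count`, `genuine_count` (no totals row).
#' @return Ledger tibble with a trailing `Total` row of column sums.
#' @export
ledger_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  req <- c("source", "sample_size", "fake_count", "genuine_count")
  if (!all(req %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(req, collapse = ", ")),
          class = "fuzzrank_input_error")
  }
  for (col in c("sample_size", "fake_count", "genuine_count")) {
    if (any(counts[[col]] != floor(counts[[col]]))) {
      abort(sprintf("`%s` must be whole numbers.", col),
            class = "fuzzrank_validation_error")
    }
    counts[[col]] <- as.integer(counts[[col]])
  }
  bad <- which(counts$sample_size != counts$fake_count + counts$genuine_count)
  if (length(bad) > 0) {
    abort(sprintf("Row %d ('%s'): sample_size != fake + genuine.",
                  bad[1], counts$source[bad[1]]),
          class = "fuzzrank_validation_error")
  }
  totals <- tibble::tibble(source = "Total",
                           sample_size = sum(counts$sample_size),
                           fake_count = sum(counts$fake_count),
                           genuine_count = sum(counts$genuine_count))
  dplyr::bind_rows(counts[req], totals)
}
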