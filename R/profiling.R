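polarity_levels <- c("strongly negative", "slightly negative", "neutral",
                     "slightly positive", "strongly positive")
subjectivity_levels <- c("low", "medium-low", "medium", "medium-high", "high")

bucketize <- function(x, breaks, labels, what, lo, hi) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo | x > hi)) {
    abort(sprintf("`%s` must be numeric in [%g, %g].", what, lo, hi),
          class = "fuzzrank_domain_error")
  }
  # left-closed/right-open intervals; the final interval is closed so the
  # mapping is total on the domain
  cut(x, breaks = breaks, labels = labels, right = FALSE,
      include.lowest = TRUE)
}

#' Bucket a polarity score into five sentiment categories
#'
#' Polarity scores (from any lexicon scorer) range from -1 (entirely
#' negative) to 1 (entirely positive) and are mapped onto five categories at
#' the cut points -0.5, -0.1, 0.1, 0.5. Cut points belong to the interval on
#' their right, and the top interval is closed, so the mapping is total and
#' deterministic.
#'
#' @param polarity Numeric vector in `[-1, 1]`.
#' @return Factor with levels strongly negative, slightly negative, neutral,
#'   slightly positive, strongly positive.
#' @export
#' @examples
#' polarity_bucket(c(-0.7, 0, 0.3))
polarity_bucket <- function(polarity) {
  bucketize(polarity, c(-1, -0.5, -0.1, 0.1, 0.5, 1), polarity_levels,
            "polarity", -1, 1)
}

#' Bucket a subjectivity score into five categories
#'
#' Subjectivity scores range from 0 (entirely objective) to 1 (entirely
#' subjective) and are mapped onto five equal-width categories; the same
#' boundary convention as [polarity_bucket()] applies.
#'
#' @param subjectivity Numeric vector in `[0, 1]`.
#' @return Factor with levels low, medium-low, medium, medium-high, high.
#' @export
#' @examples
#' subjectivity_bucket(c(0.1, 0.5, 1))
subjectivity_bucket <- function(subjectivity) {
  bucketize(subjectivity, c(0, 0.2, 0.4, 0.6, 0.8, 1), subjectivity_levels,
            "subjectivity", 0, 1)
}

#' Sentiment profile of numeric scores
#'
#' Combines numeric polarity/subjectivity scores with their categorical
#' buckets. Scoring itself is delegated to a pluggable external lexicon
#' scorer; this module consumes its numeric output.
#'
#' @param polarity Numeric vector in `[-1, 1]`.
#' @param subjectivity Numeric vector in `[0, 1]`, same length.
#' @return Tibble with columns `polarity`, `subjectivity`,
#'   `polarity_bucket`, `subjectivity_bucket`.
#' @export
sentiment_profile <- function(polarity, subjectivity) {
  stopifnot(length(polarity) == length(subjectivity))
  tibble::tibble(polarity = polarity,
                 subjectivity = subjectivity,
                 polarity_bucket = polarity_bucket(polarity),
                 subjectivity_bucket = subjectivity_bucket(subjectivity))
}

#' Keyword occurrence profile by label
#'
#' For each keyword and each label, the fraction of records whose text
#' contains the keyword as a case-insensitive substring (presence, not
#' mention counts). Useful for spotting vocabulary that disproportionately
#' marks fake texts (e.g. "immune").
#'
#' @param records Tibble with `text` and encoded `label` columns; must be
#'   non-empty.
#' @param keywords Character vector; defaults to [covid_keywords()].
#' @return Tibble with columns `keyword`, `label`, `n`, `n_with`,
#'   `fraction`.
#' @export
keyword_occurrence_profile <- function(records, keywords = covid_keywords()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    abort("Cannot profile an empty corpus.", class = "fuzzrank_input_error")
  }
  if (anyNA(records$label)) {
    abort("All records must carry an encoded label.",
          class = "fuzzrank_input_error")
  }
  txt <- normalize_text(records$text)
  purrr::map_dfr(keywords, function(kw) {
    has <- stringr::str_detect(txt, stringr::fixed(stringr::str_to_lower(kw)))
    tibble::tibble(keyword = kw, label = sort(unique(records$label))) |>
      dplyr::rowwise() |>
      dplyr::mutate(n = sum(records$label == .data$label),
                    n_with = sum(has & records$label == .data$label),
                    fraction = .data$n_with / .data$n) |>
      dplyr::ungroup()
  })
}
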