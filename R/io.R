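#' Read a corpus from CSV or JSONL
#'
#' Accepts UTF-8 CSV (columns `id`, `text`, `source`, `raw_label`) or JSON
#' Lines (one object per line with the same keys). Format is inferred from
#' the file extension unless given.
#'
#' @param path Input file.
#' @param format `"auto"`, `"csv"`, or `"jsonl"`.
#' @return Tibble with columns `id`, `text`, `source`, `raw_label`, plus
#'   `label` (`NA` until harmonized) and `cleaned = FALSE` if absent.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  rec <- if (format == "csv") {
    # trim_ws would destroy whitespace-perturbed duplicates before dedup
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    trim_ws = FALSE)
  } else {
    lines <- readr::read_lines(path, progress = FALSE)
    dplyr::bind_rows(purrr::map(lines[nzchar(lines)],
                                ~ jsonlite::fromJSON(.x)))
  }
  rec <- tibble::as_tibble(rec)
  req <- c("id", "text", "source", "raw_label")
  if (!all(req %in% names(rec))) {
    abort(paste("Corpus must provide columns:", paste(req, collapse = ", ")),
          class = "fuzzrank_input_error")
  }
  if (!"label" %in% names(rec)) rec$label <- NA_integer_
  if (!"cleaned" %in% names(rec)) rec$cleaned <- FALSE
  rec$id <- as.character(rec$id)
  rec
}

#' Write a corpus as JSON Lines
#'
#' @param records Corpus tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE)
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read per-item probability matrices
#'
#' Two formats are supported: JSON (object mapping item id -> classifier id
#' -> length-C confidence vector) and long-form CSV with columns `item`,
#' `classifier`, `class`, `confidence`.
#'
#' @param path Input file.
#' @param format `"auto"`, `"json"`, or `"csv"`.
#' @param renormalize Passed to [probability_matrix()].
#' @return Named list of [probability_matrix()] objects, one per item.
#' @export
read_probability_matrices <- function(path, format = c("auto", "json", "csv"),
                                      renormalize = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    raw <- jsonlite::read_json(path)
    out <- purrr::map(raw, function(item) {
      rows <- purrr::map(item, ~ as.numeric(unlist(.x)))
      probability_matrix(do.call(rbind, rows),
                         classifier_ids = names(item),
                         renormalize = renormalize)
    })
    return(out)
  }
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("item", "classifier", "class", "confidence")
  if (!all(req %in% names(long))) {
    abort(paste("Long CSV must provide columns:",
                paste(req, collapse = ", ")),
          class = "fuzzrank_input_error")
  }
  split(long, long$item) |>
    purrr::map(function(d) {
      wide <- tidyr::pivot_wider(d, id_cols = "classifier",
                                 names_from = "class",
                                 values_from = "confidence")
      cls <- sort(setdiff(names(wide), "classifier"))
      m <- as.matrix(wide[, cls, drop = FALSE])
      probability_matrix(m, classifier_ids = wide$classifier,
                         class_ids = cls, renormalize = renormalize)
    })
}

#' Write a fusion report
#'
#' Emits a per-item JSON report (fused scores, decision, roc score) and/or a
#' CSV summary for a [fuse_ensemble()] result.
#'
#' @param fused Tibble from [fuse_ensemble()].
#' @param json_path,csv_path Output paths; `NULL` skips that format.
#' @return `fused`, invisibly.
#' @export
write_fusion_report <- function(fused, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(fused, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) readr::write_csv(fused, csv_path)
  invisible(fused)
}

#' Write a split manifest
#'
#' @param split A [stratified_split()] result.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, test_fraction = split$test_fraction,
         train_ids = split$train_ids, test_ids = split$test_ids),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a corpus ledger as CSV
#'
#' Column order matches the published sample-size table: source, sample
#' size, fake count, genuine count.
#'
#' @param ledger Tibble from [ledger_summary()] or [ledger_from_counts()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  readr::write_csv(ledger, path)
  invisible(path)
}
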