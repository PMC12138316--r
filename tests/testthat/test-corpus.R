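test_that("clean_text strips URLs and emoji and normalizes whitespace", {
  expect_identical(clean_text("Long COVID is real https://t.co/abc \U0001F637"),
                   "Long COVID is real")
  expect_identical(clean_text("no links here"), "no links here")
  cases <- c(
    "visit www.example.com/page now" ,
    "double  spaces\tand tabs",
    "  padded  ",
    "emoji mid \U0001F9A0 sentence",
    "two \U0001F637\U0001F614 emoji",
    "HTTP://CAPS.example/x trailing",
    "flag \U0001F1FA\U0001F1F8 removed",
    "keep covid-19 hyphen",
    "url at end https://a.b/c",
    "https://lead.ing/url text",
    "plain",
    "multi\nline\ntext",
    "variation❤️ selector",
    "arrows → gone",
    "check ✅ mark",
    "wave\U0001F30A",
    "www.start",
    "mixed www.x.y \U0001F637 both",
    "number 42 stays",
    "")
  expected <- c(
    "visit now",
    "double spaces and tabs",
    "padded",
    "emoji mid sentence",
    "two emoji",
    "trailing",
    "flag removed",
    "keep covid-19 hyphen",
    "url at end",
    "text",
    "plain",
    "multi line text",
    "variation selector",
    "arrows gone",
    "check mark",
    "wave",
    "",
    "mixed both",
    "number 42 stays",
    "")
  expect_identical(clean_text(cases), expected)
})

test_that("clean_text is idempotent", {
  fixtures <- c("a https://x.y b \U0001F637", "  spaced   out  ",
                "plain text", "www.u.v \U0001F489\U0001F9A0")
  once <- clean_text(fixtures)
  expect_identical(clean_text(once), once)
})

test_that("clean_corpus flags records that become empty", {
  rec <- tibble::tibble(id = c("a", "b"),
                        text = c("ok text", "https://only.url/x"),
                        source = "synthetic", raw_label = "fake",
                        label = 1L, cleaned = FALSE)
  expect_warning(out <- clean_corpus(rec), "empty")
  expect_true(out$cleaned[1])
  expect_identical(out$empty_after_cleaning, c(FALSE, TRUE))
})

test_that("deduplicate removes case/whitespace duplicates, keeps first, stays stable", {
  rec <- tibble::tibble(id = as.character(1:3),
                        text = c("A", "a ", "B"),
                        source = "synthetic", raw_label = "fake")
  out <- deduplicate(rec)
  expect_identical(out$text, c("A", "B"))
  expect_identical(attr(out, "n_removed"), 1L)
  # identity on all-unique input, idempotent, never grows
  uniq <- tibble::tibble(id = as.character(1:4),
                         text = c("w", "x", "y", "z"))
  expect_identical(deduplicate(uniq)$text, uniq$text)
  again <- deduplicate(out)
  expect_identical(again$text, out$text)
  expect_identical(attr(again, "n_removed"), 0L)
})

test_that("planted duplicates are removed exactly", {
  g <- gen_corpus(corpus_gen_config(n_fake = 70, n_genuine = 30,
                                    duplicate_rate = 0.17, seed = 12))
  expect_identical(g$truth$n_duplicates, 17L)
  survivors <- deduplicate(clean_corpus(g$records))
  expect_identical(nrow(survivors), 83L)
  expect_identical(attr(survivors, "n_removed"), 17L)
})

test_that("keyword filter retains on case-insensitive substrings", {
  rec <- tibble::tibble(id = c("a", "b", "c"),
                        text = c("Omicron subvariant wave",
                                 "Masks reduce droplet spread",
                                 "Long-Term effects persist"))
  out <- keyword_filter(rec)
  expect_identical(out$id, c("a", "c"))
  expect_error(keyword_filter(rec, character()),
               class = "fuzzrank_config_error")
  # union of keyword lists retains a superset
  a <- keyword_filter(rec, "omicron")
  b <- keyword_filter(rec, "long-term")
  ab <- keyword_filter(rec, c("omicron", "long-term"))
  expect_true(all(a$id %in% ab$id))
  expect_true(all(b$id %in% ab$id))
})

test_that("keyword filter retention tracks planted prevalence", {
  kp <- tibble::tibble(keyword = "omicron", fake = 0.7, genuine = 0.7)
  g <- gen_corpus(corpus_gen_config(n_fake = 700, n_genuine = 300,
                                    keyword_prevalence = kp,
                                    duplicate_rate = 0, url_emoji_rate = 0,
                                    seed = 5))
  kept <- keyword_filter(g$records, "omicron")
  expect_within_binom99(nrow(kept) / 1000, 0.7, 1000)
  # and the planted flags agree exactly with the retained set
  expect_identical(sort(kept$id), sort(g$records$id[g$truth$keyword_flags[, 1]]))
})

test_that("label harmonization follows the documented source maps", {
  expect_identical(harmonize_label("PolitiFact", "mostly true"), 0L)
  expect_identical(harmonize_label("Snopes", "labeled-satire"), 1L)
  politifact <- c("true" = 0L, "mostly true" = 0L, "half-true" = 1L,
                  "barely true" = 1L, "false" = 1L, "pants-on-fire" = 1L)
  snopes <- c("true" = 0L, "mostly true" = 0L, "correct-attribution" = 0L,
              "mixture" = 1L, "mostly false" = 1L, "false" = 1L,
              "unproven" = 1L, "outdated" = 1L, "miscaptioned" = 1L,
              "misattributed" = 1L, "scam" = 1L, "legend" = 1L,
              "labeled-satire" = 1L, "lost-legend" = 1L)
  for (lbl in names(politifact)) {
    expect_identical(harmonize_label("PolitiFact", lbl),
                     unname(politifact[lbl]))
  }
  for (lbl in names(snopes)) {
    expect_identical(harmonize_label("Snopes", lbl), unname(snopes[lbl]))
  }
  # unknown labels and sources error loudly, naming the offender
  expect_error(harmonize_label("Snopes", "sideways"),
               class = "fuzzrank_mapping_error", regexp = "sideways")
  expect_error(harmonize_label("Nowhere", "true"),
               class = "fuzzrank_mapping_error", regexp = "Nowhere")
})

test_that("harmonize_labels encodes a whole corpus", {
  rec <- tibble::tibble(id = c("a", "b", "c"),
                        text = "t",
                        source = c("PolitiFact", "Snopes", "CTF"),
                        raw_label = c("pants-on-fire", "true", "fake"))
  out <- harmonize_labels(rec)
  expect_identical(out$label, c(1L, 0L, 1L))
})

test_that("stratified split reproduces the 293/2634 partition at N = 2927", {
  rec <- tibble::tibble(id = as.character(1:2927),
                        label = rep(c(1L, 0L), c(2361, 566)))
  sp <- stratified_split(rec, 0.1, seed = 4)
  expect_identical(length(sp$test_ids), 293L)
  expect_identical(length(sp$train_ids), 2634L)
  test_labels <- rec$label[match(sp$test_ids, rec$id)]
  # largest remainder: 236.1 -> 236 fake, 56.6 -> 57 genuine
  expect_identical(sum(test_labels == 1L), 236L)
  expect_identical(sum(test_labels == 0L), 57L)
})

test_that("stratified split is exact on small cases and deterministic per seed", {
  rec10 <- tibble::tibble(id = as.character(1:10),
                          label = rep(c(1L, 0L), each = 5))
  sp <- stratified_split(rec10, 0.2, seed = 1)
  lab <- rec10$label[match(sp$test_ids, rec10$id)]
  expect_identical(sort(lab), c(0L, 1L))
  # N = 101 (70 fake / 31 genuine) at 0.1: quotas 7.0 and 3.1 -> 7 + 3 = 10
  rec101 <- tibble::tibble(id = as.character(1:101),
                           label = rep(c(1L, 0L), c(70, 31)))
  sp101 <- stratified_split(rec101, 0.1, seed = 2)
  lab101 <- rec101$label[match(sp101$test_ids, rec101$id)]
  expect_identical(sum(lab101 == 1L), 7L)
  expect_identical(sum(lab101 == 0L), 3L)
  # bit-identical under the same seed; disjoint covering partition
  sp2 <- stratified_split(rec101, 0.1, seed = 2)
  expect_identical(sp101$test_ids, sp2$test_ids)
  expect_identical(sp101$train_ids, sp2$train_ids)
  expect_length(intersect(sp101$train_ids, sp101$test_ids), 0)
  expect_setequal(c(sp101$train_ids, sp101$test_ids), rec101$id)
})

test_that("per-class test share stays within one record of the fraction", {
  set.seed(8)
  for (i in 1:20) {
    nf <- sample(20:400, 1); ng <- sample(20:400, 1)
    frac <- runif(1, 0.05, 0.4)
    rec <- tibble::tibble(id = as.character(seq_len(nf + ng)),
                          label = rep(c(1L, 0L), c(nf, ng)))
    sp <- stratified_split(rec, frac, seed = i)
    lab <- rec$label[match(sp$test_ids, rec$id)]
    expect_lt(abs(sum(lab == 1L) - frac * nf), 1)
    expect_lt(abs(sum(lab == 0L) - frac * ng), 1)
  }
})

test_that("split degenerate inputs raise stratification errors", {
  one_class <- tibble::tibble(id = as.character(1:5), label = rep(1L, 5))
  expect_error(stratified_split(one_class, 0.2, 1),
               class = "fuzzrank_stratification_error")
  tiny <- tibble::tibble(id = as.character(1:30),
                         label = rep(c(1L, 0L), c(28, 2)))
  expect_error(stratified_split(tiny, 0.1, 1),
               class = "fuzzrank_stratification_error")
})

test_that("ledger aggregates per-source counts with consistent totals", {
  rec <- tibble::tibble(
    id = as.character(1:7),
    source = c("CTF", "CTF", "Snopes", "Snopes", "Snopes", "CoAID", "CoAID"),
    text = "t",
    label = c(1L, 0L, 1L, 1L, 0L, 0L, 0L))
  led <- ledger_summary(rec)
  expect_identical(led$source[nrow(led)], "Total")
  expect_true(all(led$sample_size == led$fake_count + led$genuine_count))
  totals <- led[led$source == "Total", ]
  body <- led[led$source != "Total", ]
  expect_identical(totals$sample_size, sum(body$sample_size))
  expect_identical(totals$fake_count, sum(body$fake_count))
  expect_identical(totals$genuine_count, sum(body$genuine_count))
  # empty corpus: all-zero ledger
  empty <- ledger_summary(rec[0, ])
  expect_identical(empty$sample_size, 0L)
})

test_that("ledger matches generator bookkeeping on synthetic corpora", {
  g <- gen_corpus(corpus_gen_config(n_fake = 60, n_genuine = 40, seed = 9))
  led <- ledger_summary(g$records)
  syn <- led[led$source == "synthetic", ]
  expect_identical(syn$fake_count, 60L)
  expect_identical(syn$genuine_count, 40L)
  expect_identical(syn$sample_size, 100L)
})

test_that("ledger_from_counts validates rows and computes totals", {
  counts <- tibble::tibble(source = c("A", "B"),
                           sample_size = c(10L, 5L),
                           fake_count = c(7L, 2L),
                           genuine_count = c(3L, 3L))
  led <- ledger_from_counts(counts)
  expect_identical(led$sample_size[3], 15L)
  bad <- counts; bad$sample_size[2] <- 6L
  expect_error(ledger_from_counts(bad),
               class = "fuzzrank_validation_error")
})
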