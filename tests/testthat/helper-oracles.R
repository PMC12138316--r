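# Independent straight-line oracles. These deliberately re-derive every
# quantity with explicit loops and base arithmetic, sharing no code with the
# package implementation.

oracle_fuzzy_fuse <- function(values, scale = 2) {
  K <- nrow(values)
  C <- ncol(values)
  rank_matrix <- matrix(0, K, C)
  for (k in seq_len(K)) {
    for (cc in seq_len(C)) {
      rank_matrix[k, cc] <- 1 - exp(-exp(-scale * values[k, cc]))
    }
  }
  rank_sum <- numeric(C)
  ccf <- numeric(C)
  for (cc in seq_len(C)) {
    rank_sum[cc] <- sum(rank_matrix[, cc])
    s <- 0
    for (k in seq_len(K)) s <- s + values[k, cc]
    ccf[cc] <- 1 - s / K
  }
  fused <- rank_sum * ccf
  decision_index <- which(fused == min(fused))[1]  # lowest class index on ties
  list(rank_matrix = rank_matrix, rank_sum = rank_sum, ccf = ccf,
       fused_score = fused, decision_index = decision_index)
}

oracle_auc_pairwise <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# random row-normalized K x C probability matrix
random_prob_matrix <- function(K = 3, C = 2) {
  m <- matrix(runif(K * C), K, C)
  m / rowSums(m)
}

# two-sided 99% normal-approximation binomial band around prevalence p
expect_within_binom99 <- function(observed_fraction, p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  expect_lt(abs(observed_fraction - p), max(half, 1.5 / n))
}
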