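#' Transformer architecture specification
#'
#' A minimal description of an encoder classification architecture,
#' sufficient to count its trainable parameters analytically — no weights are
#' ever downloaded or instantiated.
#'
#' Three families are supported:
#' \describe{
#'   \item{bert-like}{absolute position + token-type embeddings, biased
#'     Q/K/V/output attention projections, pooler + linear head.}
#'   \item{roberta-like}{same encoder; classification head is a dense layer
#'     plus output projection (no pooler).}
#'   \item{xlnet-like}{relative attention: five bias-free projections
#'     (q/k/v/o/r), shared r_w/r_r/r_s attention biases, binary segment
#'     embeddings, a mask embedding, no position/token-type embedding
#'     tables; sequence-summary dense + logit projection head.}
#' }
#'
#' @param family `"bert-like"`, `"roberta-like"`, or `"xlnet-like"`.
#' @param vocab_size Token vocabulary size.
#' @param hidden Hidden width H.
#' @param layers Number of encoder layers.
#' @param ffn Feed-forward inner width.
#' @param max_positions Position-embedding table length (bert/roberta
#'   families).
#' @param type_vocab Token-type vocabulary size (bert/roberta families).
#' @param heads Attention head count (required for xlnet-like).
#' @param head_dim Per-head width (required for xlnet-like;
#'   `hidden == heads * head_dim`).
#' @param num_labels Number of output classes (default 2).
#' @param head_style `"pooler+linear"`, `"dense+projection"`, or
#'   `"summary+projection"`; defaults to the family's canonical head.
#' @return An object of class `arch_spec`.
#' @export
#' @examples
#' arch_spec("bert-like", vocab_size = 30522, hidden = 768, layers = 12,
#'           ffn = 3072, max_positions = 512, type_vocab = 2)
arch_spec <- function(family = c("bert-like", "roberta-like", "xlnet-like"),
                      vocab_size, hidden, layers, ffn,
                      max_positions = NULL, type_vocab = NULL,
                      heads = NULL, head_dim = NULL,
                      num_labels = 2L, head_style = NULL) {
  family <- match.arg(family)
  if (is.null(head_style)) {
    head_style <- switch(family,
                         "bert-like" = "pooler+linear",
                         "roberta-like" = "dense+projection",
                         "xlnet-like" = "summary+projection")
  }
  head_style <- match.arg(head_style,
                          c("pooler+linear", "dense+projection",
                            "summary+projection"))
  dims <- c(vocab_size = vocab_size, hidden = hidden, layers = layers,
            ffn = ffn, num_labels = num_labels)
  if (any(!is.finite(dims)) || any(dims <= 0) || any(dims != floor(dims))) {
    abort("All architecture dimensions must be positive integers.",
          class = "fuzzrank_validation_error")
  }
  if (family %in% c("bert-like", "roberta-like")) {
    if (is.null(max_positions) || is.null(type_vocab) ||
        max_positions < 1 || type_vocab < 1) {
      abort(sprintf("%s needs positive `max_positions` and `type_vocab`.",
                    family),
            class = "fuzzrank_validation_error")
    }
  } else {
    if (is.null(heads) || is.null(head_dim)) {
      abort("xlnet-like needs `heads` and `head_dim`.",
            class = "fuzzrank_validation_error")
    }
    if (hidden != heads * head_dim) {
      abort("`hidden` must equal `heads * head_dim`.",
            class = "fuzzrank_validation_error")
    }
  }
  structure(list(family = family, vocab_size = as.integer(vocab_size),
                 hidden = as.integer(hidden), layers = as.integer(layers),
                 ffn = as.integer(ffn),
                 max_positions = if (is.null(max_positions)) NA_integer_ else as.integer(max_positions),
                 type_vocab = if (is.null(type_vocab)) NA_integer_ else as.integer(type_vocab),
                 heads = if (is.null(heads)) NA_integer_ else as.integer(heads),
                 head_dim = if (is.null(head_dim)) NA_integer_ else as.integer(head_dim),
                 num_labels = as.integer(num_labels),
                 head_style = head_style),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat("<arch_spec>", x$family, "| vocab", x$vocab_size, "| hidden", x$hidden,
      "| layers", x$layers, "| head", x$head_style, "\n")
  invisible(x)
}

#' Canonical base-size architecture presets
#'
#' Returns the architecture of the base-size checkpoint of each family as
#' used for two-class sequence classification.
#'
#' @param name `"bert-base"`, `"roberta-base"`, or `"xlnet-base"`.
#' @return An [arch_spec()].
#' @export
#' @examples
#' count_transformer_params(arch_preset("bert-base"))
arch_preset <- function(name = c("bert-base", "roberta-base", "xlnet-base")) {
  name <- match.arg(name)
  switch(name,
    "bert-base" = arch_spec("bert-like", vocab_size = 30522, hidden = 768,
                            layers = 12, ffn = 3072, max_positions = 512,
                            type_vocab = 2, num_labels = 2,
                            head_style = "pooler+linear"),
    "roberta-base" = arch_spec("roberta-like", vocab_size = 50265,
                               hidden = 768, layers = 12, ffn = 3072,
                               max_positions = 514, type_vocab = 1,
                               num_labels = 2,
                               head_style = "dense+projection"),
    "xlnet-base" = arch_spec("xlnet-like", vocab_size = 32000, hidden = 768,
                             layers = 12, ffn = 3072, heads = 12,
                             head_dim = 64, num_labels = 2,
                             head_style = "summary+projection"))
}

#' Count trainable parameters of a transformer classifier analytically
#'
#' Sums each tensor's size from the architecture description: embedding
#' tables (word, position, token type where applicable, embedding layer
#' norm), per-layer attention and feed-forward weights with their biases and
#' layer norms, and the classification head. Non-trainable buffers (e.g.
#' position-id indices) are excluded; all biases and layer-norm scales and
#' shifts are included.
#'
#' @param spec An [arch_spec()].
#' @return The exact integer count of trainable scalars (as a double, since
#'   counts exceed `.Machine$integer.max` for base-size models).
#' @export
#' @examples
#' count_transformer_params(arch_preset("roberta-base"))
count_transformer_params <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  H <- as.numeric(spec$hidden)
  FF <- as.numeric(spec$ffn)
  V <- as.numeric(spec$vocab_size)
  L <- as.numeric(spec$layers)
  nl <- as.numeric(spec$num_labels)

  ffn_block <- (H * FF + FF) + (FF * H + H) + 2 * H   # two dense + layer norm
  head_params <- switch(spec$head_style,
    # numerically identical shapes, structurally distinct heads
    "pooler+linear"      = (H * H + H) + (H * nl + nl),
    "dense+projection"   = (H * H + H) + (H * nl + nl),
    "summary+projection" = (H * H + H) + (H * nl + nl))

  if (spec$family %in% c("bert-like", "roberta-like")) {
    emb <- V * H + as.numeric(spec$max_positions) * H +
      as.numeric(spec$type_vocab) * H + 2 * H
    attn <- 4 * (H * H + H) + 2 * H   # Q/K/V/output with biases + layer norm
    total <- emb + L * (attn + ffn_block) + head_params
  } else {
    A <- as.numeric(spec$heads) * as.numeric(spec$head_dim)
    emb <- V * H + H                  # word table + mask embedding
    attn <- 5 * H * A +               # bias-free q/k/v/o/r projections
      3 * A +                         # r_w / r_r / r_s attention biases
      2 * A +                         # binary segment embeddings
      2 * H                           # attention layer norm
    total <- emb + L * (attn + ffn_block) + head_params
  }
  total
}

#' Read an architecture specification from JSON
#'
#' @param path JSON file with the fields of [arch_spec()].
#' @return An [arch_spec()].
#' @export
read_arch_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(arch_spec, x)
}
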