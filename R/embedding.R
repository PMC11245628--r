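#' Stimulus embedding container
#'
#' A `p x w` matrix of unit activations, one column per stimulus word, with
#' bookkeeping for which rows came from which model layer and which context
#' mode produced them.
#'
#' @param M numeric `p x w` matrix; all values must be finite.
#' @param layer_slices named list mapping layer name to the row indices it
#'   occupies; the slice widths must sum to `p`.
#' @param context_mode character tag (`"sentence"`, `"rolling"`, or a
#'   free-form description for synthetic embeddings).
#' @param words optional character vector of the source words (length `w`).
#' @return An object of class `stimulus_embedding`.
#' @export
stimulus_embedding <- function(M, layer_slices = list(all = seq_len(nrow(M))),
                               context_mode = "synthetic", words = NULL) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop_invalid("stimulus embedding contains non-finite values")
  if (sum(lengths(layer_slices)) != nrow(M))
    stop_invalid("layer slice widths (%d) do not sum to p = %d",
                 sum(lengths(layer_slices)), nrow(M))
  if (!is.null(words) && length(words) != ncol(M))
    stop_invalid("words length %d does not match w = %d", length(words), ncol(M))
  structure(list(M = M, layer_slices = layer_slices,
                 context_mode = context_mode, words = words),
            class = "stimulus_embedding")
}

#' @export
print.stimulus_embedding <- function(x, ...) {
  cat(sprintf("<stimulus_embedding> p = %d x w = %d (%d layer slice(s), context: %s)\n",
              nrow(x$M), ncol(x$M), length(x$layer_slices), x$context_mode))
  invisible(x)
}

#' @export
dim.stimulus_embedding <- function(x) dim(x$M)

# Deterministic 31-bit string hash (polynomial rolling hash). Used to seed
# the mock adapter so its activations are bit-reproducible functions of
# token identity, position and layer.
hash31 <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Mock contextual-language-model adapter
#'
#' A deterministic stand-in for a pretrained contextual language model,
#' used in tests and synthetic pipelines. Words are split into subword
#' tokens of at most four characters; each token's activation in each
#' layer is a hash-seeded Gaussian vector that depends on the token
#' string, its position in the input context, and the layer index, so
#' repeated calls are bit-identical. The adapter mimics the shape contract
#' of a transformer encoder: an input-embedding layer plus `n_layers`
#' transformer layers, each of width `width`.
#'
#' @param n_layers number of transformer layers (default 12).
#' @param width units per layer (default 768).
#' @param tag string mixed into the hash so distinct mock models disagree.
#' @return An adapter: a list with fields `n_layers`, `width`, `layer_names`
#'   and a function `encode(words)` returning `layers` (a list of
#'   `width x n_tokens` activation matrices, input embedding first) and
#'   `token_word` (the 1-based word index of each token).
#' @export
mock_language_adapter <- function(n_layers = 12, width = 768, tag = "mock") {
  layer_names <- c("embedding", paste0("layer_", seq_len(n_layers)))
  encode <- function(words) {
    pieces <- lapply(words, function(wd) {
      if (nchar(wd) == 0) return(character(0))
      starts <- seq(1, nchar(wd), by = 4)
      substring(wd, starts, pmin(starts + 3, nchar(wd)))
    })
    token_word <- rep(seq_along(words), lengths(pieces))
    tokens <- unlist(pieces, use.names = FALSE)
    layers <- lapply(seq_along(layer_names), function(l) {
      acts <- vapply(seq_along(tokens), function(j)
        withr::with_seed(hash31(paste(tag, tokens[j], j, l, sep = "|")),
                         rnorm(width)),
        numeric(width))
      matrix(acts, nrow = width)
    })
    list(layers = layers, token_word = token_word)
  }
  list(n_layers = n_layers, width = width, layer_names = layer_names,
       encode = encode)
}

#' Constant adapter returning all-ones activations
#'
#' A degenerate adapter for contract tests: every token's activation in
#' every layer is a vector of ones.
#'
#' @inheritParams mock_language_adapter
#' @return An adapter with the same interface as [mock_language_adapter()].
#' @export
constant_adapter <- function(n_layers = 2, width = 4) {
  layer_names <- c("embedding", paste0("layer_", seq_len(n_layers)))
  encode <- function(words) {
    token_word <- seq_along(words)
    layers <- lapply(layer_names, function(l)
      matrix(1, nrow = width, ncol = length(words)))
    list(layers = layers, token_word = token_word)
  }
  list(n_layers = n_layers, width = width, layer_names = layer_names,
       encode = encode)
}

#' Pool subword-token activations to one activation per word
#'
#' @param acts `units x n_tokens` activation matrix.
#' @param token_word integer vector, the 1-based word index of each token;
#'   every word in `1:n_words` must receive at least one token.
#' @param n_words number of words expected.
#' @param policy `"mean"` (default), `"first"`, or `"last"`.
#' @return `units x n_words` matrix.
#' @export
pool_subword_tokens <- function(acts, token_word, n_words,
                                policy = c("mean", "first", "last")) {
  policy <- match.arg(policy)
  counts <- tabulate(token_word, nbins = n_words)
  if (any(counts == 0))
    stop_invalid("alignment error: word %d received no tokens", which(counts == 0)[1])
  out <- matrix(0, nrow(acts), n_words)
  for (k in seq_len(n_words)) {
    cols <- which(token_word == k)
    out[, k] <- switch(policy,
                       mean = rowMeans(acts[, cols, drop = FALSE]),
                       first = acts[, cols[1]],
                       last = acts[, cols[length(cols)]])
  }
  out
}

#' Extract a stimulus embedding from a word sequence
#'
#' Feeds the stimulus to a contextual-language-model adapter and assembles
#' a `p x w` embedding with one column per word. With
#' `context_mode = "sentence"` each sentence (as given by the sequence's
#' sentence ids) is encoded as one input context. With `"rolling"`, each
#' word is encoded inside a sentence-free trailing window of `window`
#' words ending at that word, and its own activation is taken from that
#' context. Subword-token activations are pooled per word.
#'
#' @param seq a [word_sequence()].
#' @param adapter an adapter such as [mock_language_adapter()].
#' @param context_mode `"sentence"` or `"rolling"`.
#' @param layers_used `"all"` to stack the input-embedding layer plus every
#'   transformer layer, or a single integer `k` to keep transformer layer
#'   `k` only (0 = the input-embedding layer).
#' @param window rolling-context window length in words (default 64).
#' @param pool subword pooling policy, see [pool_subword_tokens()].
#' @return A [stimulus_embedding()].
#' @export
extract_embeddings <- function(seq, adapter,
                               context_mode = c("sentence", "rolling"),
                               layers_used = "all", window = 64,
                               pool = "mean") {
  context_mode <- match.arg(context_mode)
  w <- length(seq)
  if (w == 0) stop_invalid("cannot embed an empty word sequence")
  if (identical(layers_used, "all")) {
    keep <- seq_along(adapter$layer_names)
  } else {
    k <- as.integer(layers_used)
    if (k < 0 || k > adapter$n_layers)
      stop_invalid("layers_used must be 'all' or a layer index in 0..%d", adapter$n_layers)
    keep <- k + 1L  # slot 1 is the input-embedding layer
  }
  p_layer <- adapter$width
  p <- length(keep) * p_layer
  M <- matrix(NA_real_, p, w)

  encode_span <- function(word_idx, take_idx) {
    enc <- adapter$encode(seq$words[word_idx])
    pooled <- lapply(enc$layers[keep], function(acts) {
      if (ncol(acts) != length(enc$token_word))
        stop_invalid("adapter returned %d activations for %d tokens",
                     ncol(acts), length(enc$token_word))
      pool_subword_tokens(acts, enc$token_word, length(word_idx), pool)
    })
    stacked <- do.call(rbind, pooled)
    M[, word_idx[take_idx]] <<- stacked[, take_idx, drop = FALSE]
  }

  if (context_mode == "sentence") {
    for (sid in unique(seq$sentence_ids)) {
      idx <- which(seq$sentence_ids == sid)
      encode_span(idx, seq_along(idx))
    }
  } else {
    for (k in seq_len(w)) {
      idx <- max(1L, k - window + 1L):k
      encode_span(idx, length(idx))
    }
  }
  if (anyNA(M)) stop_invalid("alignment error: word %d has no embedding",
                             which(colSums(is.na(M)) > 0)[1])
  slices <- split(seq_len(p), rep(seq_along(keep), each = p_layer))
  names(slices) <- adapter$layer_names[keep]
  stimulus_embedding(M, layer_slices = slices, context_mode = context_mode,
                     words = seq$words)
}
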