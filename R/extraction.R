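#' Causal context windows for every word
#'
#' For word i of sentence s, the context is every word of the (up to)
#' `n_context_sentences` sentences preceding s in presentation order, plus
#' words 1..i of s itself — never any future word. Given the running
#' example "THE CAT IS ON THE MAT", the context used for "ON" is
#' "THE CAT IS ON". Contexts do not cross run boundaries; they do cross
#' block boundaries (sentences are units of one presentation stream).
#'
#' @param stimuli A [stimulus_set()] in presentation order.
#' @param n_context_sentences Number of preceding sentences retained
#'   (default 3).
#' @return A list, one character vector of (case-folded) tokens per word;
#'   the last element of each vector is the word itself.
#' @export
causal_contexts <- function(stimuli, n_context_sentences = 3L) {
  tokens <- tolower(stimuli$token)
  sent <- stimuli$sentence_id
  run <- stimuli$run_id
  sent_order <- unique(sent)
  lapply(seq_len(nrow(stimuli)), function(i) {
    s_pos <- match(sent[i], sent_order)
    keep_sent <- sent_order[seq(max(1L, s_pos - n_context_sentences),
                                s_pos - 1L)]
    if (s_pos == 1L) keep_sent <- integer(0)
    prev <- which(sent %in% keep_sent & run == run[i])
    cur <- which(sent == sent[i])
    cur <- cur[cur <= i]
    tokens[c(prev, cur)]
  })
}

#' Toy contextual activation provider
#'
#' A deterministic stand-in for a trained transformer, honouring the same
#' extraction contract: given an ordered token sequence it returns one
#' vector per layer for the final token. Layer 0 is a seeded hash-based
#' word lookup (non-contextual); layer l is the unit-normalized causal
#' exponential mixture of the layer-(l-1) vectors of the sequence, with a
#' mixing rate that grows with depth so deeper layers integrate more
#' context.
#'
#' @param dim Output dimensionality (constant across layers and calls).
#' @param n_layers Number of contextual layers; the provider emits layers
#'   0..`n_layers`.
#' @param mixing_rate Context-integration rate in \[0, 1) at the deepest
#'   layer; layer l uses `mixing_rate * l / n_layers`.
#' @param seed Integer seed for the lookup table.
#' @return An `activation_provider`: a list with `$dim`, `$n_layers`, and
#'   `$layers(tokens)` returning a `(n_layers + 1) x dim` matrix (row l + 1
#'   = layer l vector for the final token).
#' @export
toy_contextual_provider <- function(dim = 16L, n_layers = 3L,
                                    mixing_rate = 0.6, seed = 1L) {
  stopifnot(mixing_rate >= 0, mixing_rate < 1, n_layers >= 1)
  lookup <- function(tok) {
    with_seed(string_hash(tolower(tok), seed), rnorm(dim))
  }
  layers <- function(tokens) {
    v <- do.call(rbind, lapply(tokens, lookup))   # layer 0, all positions
    out <- matrix(0, n_layers + 1L, dim)
    out[1, ] <- v[nrow(v), ]
    for (l in seq_len(n_layers)) {
      rho <- mixing_rate * l / n_layers
      mixed <- matrix(0, nrow(v), dim)
      acc <- rep(0, dim)
      for (i in seq_len(nrow(v))) {
        acc <- rho * acc + v[i, ]
        nrm <- sqrt(sum(acc^2))
        mixed[i, ] <- if (nrm > 0) acc / nrm else acc
      }
      out[l + 1L, ] <- mixed[nrow(v), ]
      v <- mixed
    }
    out
  }
  structure(list(dim = as.integer(dim), n_layers = as.integer(n_layers),
                 layers = layers, seed = as.integer(seed)),
            class = "activation_provider")
}

#' Extract per-layer embeddings for a stimulus set
#'
#' Runs the provider over the causal context of every word and assembles
#' one [embedding_matrix()] per layer: row i of layer l is the provider's
#' layer-l vector for word i given its context. Word-level alignment is
#' carried through, and dimensionality drift across calls is a contract
#' error.
#'
#' @param provider An activation provider (see [toy_contextual_provider()]).
#' @param stimuli A [stimulus_set()].
#' @param n_context_sentences Context window in sentences (default 3).
#' @param card_template Optional [model_card()] fields (`task`, `n_heads`,
#'   `training_step`, `accuracy_top1`) attached to the output cards.
#' @return A list of [embedding_matrix()], names `layer0`, `layer1`, ...
#' @export
extract_activations <- function(provider, stimuli, n_context_sentences = 3L,
                                card_template = list()) {
  stopifnot(inherits(provider, "activation_provider"))
  contexts <- causal_contexts(stimuli, n_context_sentences)
  n_layers <- provider$n_layers
  acts <- lapply(contexts, function(ctx) {
    m <- provider$layers(ctx)
    if (!is.matrix(m) || nrow(m) != n_layers + 1L || ncol(m) != provider$dim) {
      stop("provider contract error: layer output dimensionality drifted",
           call. = FALSE)
    }
    m
  })
  lapply(setNames(0:n_layers, paste0("layer", 0:n_layers)), function(l) {
    vals <- do.call(rbind, lapply(acts, function(m) m[l + 1L, ]))
    card <- model_card(
      task = card_template$task %||% "causal",
      n_layers = n_layers, dim = provider$dim,
      n_heads = card_template$n_heads %||% 4L,
      training_step = card_template$training_step %||% 0,
      accuracy_top1 = card_template$accuracy_top1 %||% 0,
      layer_index = l)
    embedding_matrix(vals, stimuli$word_id, card)
  })
}

#' Toy visual (word-form) embedding
#'
#' Deterministic character-recognition stand-in: each token is described by
#' word length and hashed character-bigram counts, projected to `dim`
#' dimensions with a seeded random map. Identical word forms always get
#' identical rows; no context enters.
#'
#' @param stimuli A [stimulus_set()].
#' @param dim Output dimensionality.
#' @param seed Integer seed for the projection.
#' @return An [embedding_matrix()] whose card has `task = "visual"`.
#' @export
toy_visual_provider <- function(stimuli, dim = 16L, seed = 1L) {
  vals <- visual_lookup(tolower(stimuli$token), dim, seed)
  card <- model_card("visual", n_layers = 1L, dim = dim, n_heads = 0L,
                     training_step = 0, accuracy_top1 = 0, layer_index = 0L)
  embedding_matrix(vals, stimuli$word_id, card)
}

#' Middle layers of a transformer stack
#'
#' The layers l in \[n_layers / 2, 3 n_layers / 4\], both bounds inclusive
#' over integer layer indices — the depth band where encoding performance
#' peaks (e.g. layers 6--9 of a 12-layer model).
#'
#' @param n_layers Number of contextual layers (>= 2).
#' @return Integer vector of layer indices.
#' @export
middle_layers <- function(n_layers) {
  lo <- ceiling(n_layers / 2)
  hi <- floor(3 * n_layers / 4)
  if (n_layers < 2 || hi < lo) {
    stop("middle layers undefined for n_layers = ", n_layers, call. = FALSE)
  }
  seq.int(lo, hi)
}
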