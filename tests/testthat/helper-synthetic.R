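# deterministic toy stimulus sets built directly (no sampling)

toy_stimuli <- function(tokens_by_sentence, word_gap = 0.651,
                        sentence_gap = 5, block_size = 5L,
                        subjects = list(0L)) {
  n_sent <- length(tokens_by_sentence)
  rows <- list()
  t_cur <- 0
  wid <- 0L
  for (s in seq_len(n_sent)) {
    toks <- tokens_by_sentence[[s]]
    for (tok in toks) {
      rows[[length(rows) + 1L]] <- data.frame(
        word_id = wid, token = tok, onset = t_cur, duration = 0.351,
        sentence_id = s - 1L, block_id = (s - 1L) %/% block_size,
        run_id = 0L, stringsAsFactors = FALSE)
      wid <- wid + 1L
      t_cur <- t_cur + word_gap
    }
    t_cur <- t_cur + sentence_gap
  }
  df <- do.call(rbind, rows)
  df$subjects <- rep(subjects, length.out = nrow(df))
  stimulus_set(tibble::as_tibble(df), block_size = block_size)
}

# stimuli with enough blocks for 5-fold CV, deterministic word grid
grid_stimuli <- function(n_sentences = 25L, words_each = 8L,
                         subjects = list(0L)) {
  toks <- lapply(seq_len(n_sentences), function(s) {
    sprintf("tok%02d", ((s * 3 + seq_len(words_each)) %% 40) + 1L)
  })
  toy_stimuli(toks, subjects = subjects)
}

random_card <- function(layer_index = 1L, n_layers = 4L, acc = 0.3,
                        step = 1000, task = "causal") {
  model_card(task, n_layers, 16L, 4L, step, acc, layer_index)
}
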