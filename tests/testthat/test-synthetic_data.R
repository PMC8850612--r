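test_that("stimulus generator respects protocol structure and determinism", {
  stim <- make_stimuli(n_sentences = 10, seed = 7)
  expect_equal(length(unique(stim$block_id)), 2L)     # 10 sentences / 5
  counts <- table(stim$sentence_id)
  expect_true(all(counts >= 9 & counts <= 15))
  expect_identical(make_stimuli(n_sentences = 10, seed = 7), stim)
  expect_false(identical(make_stimuli(n_sentences = 10, seed = 8), stim))
  expect_error(make_stimuli(n_sentences = 5, sentences_per_subject = 6),
               "config error")
})

test_that("sampled word durations match the configured 351 ms mean", {
  # Monte-Carlo check of the duration sampler: mean over ~1e4 words
  stim <- make_stimuli(n_sentences = 900, vocab_size = 200, seed = 11)
  n <- nrow(stim)
  expect_gt(n, 1e4 * 0.9)
  se <- sd(stim$duration) / sqrt(n)
  expect_lt(abs(mean(stim$duration) - 0.351), 3 * se)
  expect_true(all(stim$duration >= 0.300))
})

test_that("onsets encode word gaps and 5 s sentence gaps", {
  stim <- make_stimuli(n_sentences = 6, seed = 3)
  gaps <- diff(stim$onset)
  new_sentence <- diff(stim$sentence_id) != 0
  expect_true(all(gaps[new_sentence] > 5))
  # within sentences the gap is duration + 300 ms
  expect_equal(gaps[!new_sentence],
               (stim$duration[-nrow(stim)] + 0.3)[!new_sentence],
               tolerance = 1e-12)
})

test_that("embedding family plants the three signal levels", {
  stim <- make_stimuli(n_sentences = 15, seed = 5)
  fam <- make_embedding_family(stim, dim = 12, n_layers = 3, n_steps = 2,
                               signal_mix_curve = c(0, 1), seed = 9)
  # alpha = 0: values independent of word identity
  noise_emb <- fam$embeddings[["step01_layer00"]]
  lex <- fam$truth$lexical
  cors <- abs(cor(unclass(noise_emb), lex))
  # mean |corr| under independence ~ sqrt(2/(pi n)); 3 SE bound on the mean
  n <- nrow(stim)
  exp_abs <- sqrt(2 / (pi * (n - 1)))
  se <- sqrt((1 - 2 / pi) / (n - 1)) / sqrt(length(cors))
  expect_lt(mean(cors), exp_abs + 3 * se)
  # alpha = 1, layer 0: pure type-level lookup
  lookup_emb <- fam$embeddings[["step02_layer00"]]
  dup <- which(duplicated(stim$token))[1]
  first <- match(stim$token[dup], stim$token)
  expect_equal(unclass(lookup_emb)[dup, ], unclass(lookup_emb)[first, ])
  # alpha = 1, deepest layer: causal decaying average of lexical vectors
  deep <- fam$embeddings[["step02_layer03"]]
  decay <- fam$truth$decay
  for (w in c(5L, 20L, 60L)) {
    idx <- which(stim$sentence_id == stim$sentence_id[w] &
                   stim$word_id <= stim$word_id[w])
    weights <- decay^(rev(seq_along(idx)) - 1)
    recomputed <- colSums(weights * lex[idx, , drop = FALSE])
    expect_gt(cor(unclass(deep)[w, ], recomputed), 0.99)
  }
})

test_that("non-monotone mix curve is rejected when monotone is required", {
  stim <- make_stimuli(n_sentences = 10, seed = 5)
  expect_error(make_embedding_family(stim, n_steps = 3,
                                     signal_mix_curve = c(0.5, 0.2, 1)),
               "non-decreasing")
  fam <- make_embedding_family(stim, n_steps = 3,
                               signal_mix_curve = c(0.5, 0.2, 1),
                               monotone = FALSE, seed = 1)
  expect_equal(length(fam$embeddings), 3 * 4)
})

test_that("noise-free brain responses equal the forward-model prediction", {
  stim <- make_stimuli(n_sentences = 15, seed = 2)
  fam <- make_embedding_family(stim, dim = 8, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 2)
  gen <- fam$embeddings[["step01_layer02"]]
  b <- make_brain(stim, gen, n_subjects = 2, n_channels = 10, snr = Inf,
                  modality = "meg", seed = 4)
  tr <- b$truth
  peak <- which.max(tr$kernel_curve)
  expected <- scale(unclass(gen)) %*% tr$G
  expect_equal(b$recordings[[1]]$data[, , peak], expected, tolerance = 1e-12)
  expect_identical(b$recordings[[1]]$data, b$recordings[[2]]$data)
  # pre-onset samples carry no signal
  pre <- which(b$recordings[[1]]$times < 0)
  expect_true(all(b$recordings[[1]]$data[, , pre] == 0))
})

test_that("non-responsive channels are pure noise", {
  stim <- make_stimuli(n_sentences = 20, seed = 6)
  fam <- make_embedding_family(stim, dim = 8, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 6)
  gen <- fam$embeddings[["step01_layer02"]]
  b <- make_brain(stim, gen, n_subjects = 1, n_channels = 20,
                  responsive_fraction = 0.4, snr = 5, modality = "meg",
                  shared_noise_fraction = 0, seed = 8)
  peak <- which.max(b$truth$kernel_curve)
  Y <- b$recordings[[1]]$data[, , peak]
  feats <- scale(unclass(gen)) %*% b$truth$G[, b$truth$responsive, drop = FALSE]
  n <- nrow(Y)
  se <- 1 / sqrt(n - 3)                              # Fisher-z SE of r under null
  for (ch in which(!b$truth$responsive)[1:3]) {
    rs <- cor(Y[, ch], feats)
    expect_true(all(abs(atanh(rs)) < 3 * se + 1e-9))
  }
})

test_that("achieved SNR tracks the request and seeds give bit-identical data", {
  stim <- make_stimuli(n_sentences = 60, seed = 10)   # >= 500 words
  fam <- make_embedding_family(stim, dim = 8, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 10)
  gen <- fam$embeddings[["step01_layer02"]]
  b1 <- make_brain(stim, gen, n_subjects = 1, n_channels = 12, snr = 2,
                   modality = "meg", shared_noise_fraction = 0, seed = 3)
  b2 <- make_brain(stim, gen, n_subjects = 1, n_channels = 12, snr = 2,
                   modality = "meg", shared_noise_fraction = 0, seed = 3)
  expect_identical(b1$recordings[[1]]$data, b2$recordings[[1]]$data)
  peak <- which.max(b1$truth$kernel_curve)
  Y <- b1$recordings[[1]]$data[, , peak]
  sig <- b1$truth$signal_peak
  for (ch in which(b1$truth$responsive)) {
    achieved <- var(sig[, ch]) / var(Y[, ch] - sig[, ch])
    expect_lt(abs(achieved - 2) / 2, 0.10)
  }
  expect_error(make_brain(stim, gen, responsive_fraction = 0), "config error")
  expect_error(make_brain(stim, gen, snr = -1), "config error")
})

test_that("shared noise induces positive inter-subject correlation", {
  stim <- make_stimuli(n_sentences = 40, seed = 12)
  fam <- make_embedding_family(stim, dim = 8, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 12)
  gen <- fam$embeddings[["step01_layer02"]]
  b <- make_brain(stim, gen, n_subjects = 4, n_channels = 10, snr = 1,
                  modality = "meg", shared_noise_fraction = 0.5, seed = 13)
  peak <- which.max(b$truth$kernel_curve)
  resp <- which(b$truth$responsive)
  rs <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    for (ch in resp) {
      rs <- c(rs, cor(b$recordings[[i]]$data[, ch, peak],
                      b$recordings[[j]]$data[, ch, peak]))
    }
  }
  se <- sd(rs) / sqrt(length(rs))
  expect_gt(mean(rs), 3 * se)
})
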