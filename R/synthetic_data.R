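#' Planted ground truth of a synthetic dataset
#'
#' Records exactly what the generators used: the linear forward map G
#' (dimensions x channels), the responsive-channel mask, the planted
#' accuracy curve over training steps, the hemodynamic / latency kernel,
#' the per-subject SNR and all seeds. Downstream recovery tests compare
#' against these fields.
#'
#' @param ... Named ground-truth fields.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(...) structure(list(...), class = "ground_truth")

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a word-by-word stimulus stream
#'
#' Emulates a rapid serial visual presentation protocol: sentences of
#' 9--15 words, each word flashed for a mean of 351 ms (shifted-gamma
#' durations floored at 300 ms), followed by a 300 ms blank; sentences
#' separated by a 5 s blank and grouped into blocks of five consecutive
#' sentences (the cross-validation unit). Each subject is assigned a random
#' subset of sentences.
#'
#' @param n_sentences Number of sentences.
#' @param words_per_sentence Integer range `c(min, max)` of words per
#'   sentence (default 9--15).
#' @param word_duration_mean Mean word duration in seconds (default 0.351).
#' @param word_duration_min Floor of the duration distribution (default 0.3).
#' @param gap Blank between words, seconds (default 0.3).
#' @param inter_sequence_gap Blank between sentences, seconds (default 5).
#' @param block_size Sentences per block (default 5).
#' @param n_subjects Number of subjects to assign.
#' @param sentences_per_subject Sentences seen by each subject (default all).
#' @param vocab_size Word-type vocabulary size; tokens are drawn with
#'   Zipf-like weights so types repeat.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return A [stimulus_set()].
#' @export
make_stimuli <- function(n_sentences = 40, words_per_sentence = c(9L, 15L),
                         word_duration_mean = 0.351,
                         word_duration_min = 0.300, gap = 0.300,
                         inter_sequence_gap = 5, block_size = 5L,
                         n_subjects = 1L,
                         sentences_per_subject = n_sentences,
                         vocab_size = 120L, seed = 1L) {
  if (sentences_per_subject > n_sentences) {
    stop("config error: sentences_per_subject exceeds n_sentences",
         call. = FALSE)
  }
  if (words_per_sentence[1] < 1 ||
      words_per_sentence[2] < words_per_sentence[1]) {
    stop("config error: invalid words_per_sentence range", call. = FALSE)
  }
  if (word_duration_mean <= word_duration_min) {
    stop("config error: word_duration_mean must exceed the floor",
         call. = FALSE)
  }
  with_seed(seed, {
    vocab <- sprintf("w%03d", seq_len(vocab_size))
    zipf <- 1 / seq_len(vocab_size)
    n_words_sent <- sample(seq(words_per_sentence[1], words_per_sentence[2]),
                           n_sentences, replace = TRUE)
    n_words <- sum(n_words_sent)
    tokens <- sample(vocab, n_words, replace = TRUE, prob = zipf)
    # shifted gamma: floor + gamma(shape 2) with the configured mean
    durations <- word_duration_min +
      rgamma(n_words, shape = 2,
             scale = (word_duration_mean - word_duration_min) / 2)
    sentence_id <- rep(seq_len(n_sentences) - 1L, n_words_sent)
    block_id <- sentence_id %/% as.integer(block_size)
    onset <- numeric(n_words)
    t_cur <- 0
    for (i in seq_len(n_words)) {
      onset[i] <- t_cur
      t_cur <- t_cur + durations[i] + gap
      if (i < n_words && sentence_id[i + 1] != sentence_id[i]) {
        t_cur <- t_cur + inter_sequence_gap
      }
    }
    assign_by_sentence <- lapply(seq_len(n_subjects), function(s) {
      sort(sample(seq_len(n_sentences) - 1L, sentences_per_subject))
    })
    subj_of_sentence <- lapply(seq_len(n_sentences) - 1L, function(sid) {
      which(vapply(assign_by_sentence, function(a) sid %in% a, TRUE))
    })
    stimulus_set(tibble::tibble(
      word_id = seq_len(n_words) - 1L, token = tokens, onset = onset,
      duration = durations, sentence_id = sentence_id, block_id = block_id,
      run_id = 0L, subjects = subj_of_sentence[sentence_id + 1L]),
      block_size = block_size)
  })
}

## token-level deterministic vectors -------------------------------------

lexical_lookup <- function(tokens, dim, seed) {
  types <- unique(tokens)
  tab <- do.call(rbind, lapply(types, function(tok) {
    with_seed(string_hash(tok, seed), rnorm(dim))
  }))
  rownames(tab) <- types
  out <- tab[tokens, , drop = FALSE]
  rownames(out) <- NULL
  out
}

word_form_features <- function(token, n_buckets = 8L) {
  chars <- strsplit(token, "")[[1]]
  bigrams <- if (length(chars) > 1) {
    paste0(head(chars, -1), tail(chars, -1))
  } else chars
  f <- numeric(n_buckets)
  for (b in bigrams) {
    f[(string_hash(b) %% n_buckets) + 1L] <- f[(string_hash(b) %% n_buckets) + 1L] + 1
  }
  c(nchar(token), f)
}

visual_lookup <- function(tokens, dim, seed) {
  raw <- t(vapply(tokens, word_form_features, numeric(9L)))
  proj <- with_seed(seed + 17L, matrix(rnorm(9L * dim), 9L, dim) / sqrt(9))
  raw %*% proj
}

row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

## causal decaying average of lexical vectors within each sentence
compositional_signal <- function(lex, sentence_id, decay) {
  comp <- matrix(0, nrow(lex), ncol(lex))
  for (s in unique(sentence_id)) {
    idx <- which(sentence_id == s)
    acc <- rep(0, ncol(lex))
    for (k in seq_along(idx)) {
      acc <- decay * acc + lex[idx[k], ]
      comp[idx[k], ] <- acc
    }
  }
  comp
}

#' Generate a family of embeddings with a planted accuracy curve
#'
#' Emulates the representations of a family of language models frozen at
#' successive training checkpoints, without training anything. The planted
#' signal nests three levels: visual-like word-form features and a
#' lexical-like word-identity lookup (mixed at layer 0), and a
#' compositional-like signal (causal exponentially decaying average of the
#' lexical vectors over the sentence so far) that is mixed in increasingly
#' with layer depth. Checkpoint t interpolates
#' `values = (1 - alpha_t) * noise + alpha_t * signal`, and the planted
#' top-1 accuracy is a fixed monotone map of `alpha_t`, so better "trained"
#' checkpoints carry more recoverable signal.
#'
#' @param stimuli A [stimulus_set()].
#' @param dim Embedding dimensionality.
#' @param n_layers Number of contextual layers; layers 0..`n_layers` are
#'   generated (0 = word-embedding lookup).
#' @param n_steps Number of training checkpoints.
#' @param signal_mix_curve Numeric vector of length `n_steps` in \[0, 1\];
#'   default an increasing ramp. Must be non-decreasing when
#'   `monotone = TRUE`.
#' @param decay Decay of the compositional average (default 0.5).
#' @param visual_weight Weight of the word-form component inside the
#'   layer-0 signal (default 0.2).
#' @param task,n_heads Model-card metadata for the family.
#' @param monotone Require a non-decreasing mix curve (default TRUE).
#' @param max_accuracy Planted accuracy at `alpha = 1` (default 0.46,
#'   the top-1 ceiling of well-trained causal models).
#' @param seed Integer seed.
#' @return A list with `embeddings` (a list of [embedding_matrix()], one per
#'   checkpoint x layer) and `truth` (a [ground_truth()] recording the
#'   lexical table, the mix curve and the planted accuracies).
#' @export
make_embedding_family <- function(stimuli, dim = 16L, n_layers = 3L,
                                  n_steps = 10L, signal_mix_curve = NULL,
                                  decay = 0.5, visual_weight = 0.2,
                                  task = "causal", n_heads = 4L,
                                  monotone = TRUE, max_accuracy = 0.46,
                                  seed = 1L) {
  if (n_steps < 1) stop("config error: n_steps must be >= 1", call. = FALSE)
  alpha <- signal_mix_curve %||% seq(0.05, 1, length.out = n_steps)
  if (length(alpha) != n_steps) {
    stop("config error: signal_mix_curve length must equal n_steps",
         call. = FALSE)
  }
  if (monotone && any(diff(alpha) < 0)) {
    stop("config error: signal_mix_curve must be non-decreasing",
         call. = FALSE)
  }
  lex <- lexical_lookup(stimuli$token, dim, seed)
  vis <- visual_lookup(stimuli$token, dim, seed)
  base0 <- (1 - visual_weight) * row_normalize(lex) +
    visual_weight * row_normalize(vis)
  comp <- row_normalize(compositional_signal(lex, stimuli$sentence_id, decay))
  steps <- round(c(0, 10^seq(3, log10(4.5e6), length.out = max(n_steps - 1, 1))))
  embeddings <- list()
  for (t in seq_len(n_steps)) {
    for (l in 0:n_layers) {
      p <- l / n_layers
      signal <- (1 - p) * base0 + p * comp
      noise <- with_seed(seed + 1009L * t + l,
                         matrix(rnorm(length(signal), sd = sd(signal)),
                                nrow(signal), ncol(signal)))
      vals <- (1 - alpha[t]) * noise + alpha[t] * signal
      card <- model_card(task, n_layers, dim, n_heads,
                         training_step = steps[t],
                         accuracy_top1 = max_accuracy * alpha[t],
                         layer_index = l)
      embeddings[[sprintf("step%02d_layer%02d", t, l)]] <-
        embedding_matrix(vals, stimuli$word_id, card)
    }
  }
  list(embeddings = embeddings,
       truth = ground_truth(signal_mix_curve = alpha,
                            accuracy = max_accuracy * alpha,
                            training_step = steps, decay = decay,
                            visual_weight = visual_weight,
                            lexical = lex, compositional = comp,
                            seed = seed))
}

## kernels ----------------------------------------------------------------

fmri_kernel_weights <- function(kernel, delays) {
  type <- kernel$type %||% "onehot"
  if (type == "onehot") {
    w <- as.numeric(delays == kernel$delay)
    if (sum(w) != 1) {
      stop("config error: one-hot kernel delay must be one of the FIR delays",
           call. = FALSE)
    }
  } else if (type == "gamma") {
    w <- stats::dgamma(delays, shape = kernel$shape %||% 6,
                       rate = kernel$rate %||% 1)
    w <- w / sum(w)
  } else stop("config error: unknown fmri kernel type", call. = FALSE)
  w
}

meg_kernel <- function(kernel, times) {
  latency <- kernel$latency %||% 0.4
  width <- kernel$width %||% 0.12
  k <- exp(-(times - latency)^2 / (2 * width^2))
  k[times < 0] <- 0                      # causal: nothing before word onset
  if (max(k) > 0) k <- k / max(k)
  k
}

#' Generate multi-subject brain recordings from a designated embedding
#'
#' A shared linear forward model: word features (the z-scored generator
#' embedding) are projected through a common map G (dimensions x channels)
#' whose columns are zeroed for non-responsive channels, convolved with a
#' temporal kernel, and corrupted with per-subject noise plus a noise
#' component shared across subjects (which induces the positive
#' inter-subject correlation a noise ceiling feeds on).
#'
#' In fMRI mode the signal lives on the scanner grid: word features are
#' summed into TR bins and delayed by a one-hot FIR kernel (exact ground
#' truth for delay-recovery tests; a smooth gamma kernel is available). In
#' MEG mode each word epoch carries the projected features times a causal
#' Gaussian latency kernel (zero before word onset). Noise is scaled per
#' channel so that the signal-to-noise variance ratio on responsive
#' channels matches `snr` (referenced at the kernel peak in MEG mode);
#' `snr = Inf` yields noise-free recordings.
#'
#' @param stimuli A [stimulus_set()].
#' @param generator The [embedding_matrix()] driving the responses.
#' @param n_subjects,n_channels Number of subjects and channels/voxels.
#' @param responsive_fraction Fraction of channels receiving signal, in
#'   (0, 1\].
#' @param snr Signal-to-noise variance ratio on responsive channels (> 0,
#'   may be `Inf`).
#' @param modality `"fmri"` or `"meg"`.
#' @param tr fMRI repetition time, seconds.
#' @param kernel fMRI: `list(type = "onehot", delay = 4)` (seconds, one of
#'   the FIR delays) or `list(type = "gamma", shape, rate)`; MEG:
#'   `list(latency = 0.4, width = 0.12)`.
#' @param delays FIR delay grid used for the fMRI one-hot kernel.
#' @param times MEG epoch time axis (default \eqn{-0.5 \ldots 2} s at 10 Hz).
#' @param shared_noise_fraction Fraction of noise variance shared across
#'   subjects, in \[0, 1\].
#' @param ar1 AR(1) coefficient of the noise (0 = white, the default).
#' @param seed Integer seed.
#' @return A list with `recordings` (list of [brain_recording()]) and
#'   `truth` (a [ground_truth()] with G, the responsive mask, the kernel
#'   and the seeds).
#' @export
make_brain <- function(stimuli, generator, n_subjects = 4L,
                       n_channels = 20L, responsive_fraction = 0.5,
                       snr = 1, modality = c("meg", "fmri"), tr = 2,
                       kernel = NULL, delays = c(2, 4, 6, 8, 10),
                       times = seq(-0.5, 2, by = 0.1),
                       shared_noise_fraction = 0.3, ar1 = 0, seed = 1L) {
  modality <- match.arg(modality)
  if (responsive_fraction <= 0 || responsive_fraction > 1) {
    stop("config error: responsive_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (snr <= 0) stop("config error: snr must be > 0", call. = FALSE)
  check_alignment(generator, stimuli)
  Fx <- scale(unclass(generator))
  Fx[is.nan(Fx)] <- 0
  o <- ncol(Fx)
  n_responsive <- max(1L, round(responsive_fraction * n_channels))
  G <- with_seed(seed, matrix(rnorm(o * n_channels), o, n_channels) / sqrt(o))
  responsive <- rep(FALSE, n_channels)
  responsive[with_seed(seed + 1L, sample(n_channels, n_responsive))] <- TRUE
  G[, !responsive] <- 0

  colour_noise <- function(eps) {
    if (ar1 == 0) return(eps)
    flt <- apply(eps, 2, function(e) {
      as.numeric(stats::filter(e, ar1, method = "recursive"))
    })
    flt * rep(1 / apply(flt, 2, sd), each = nrow(flt))
  }

  if (modality == "fmri") {
    kernel <- kernel %||% list(type = "onehot", delay = 4)
    w <- fmri_kernel_weights(kernel, delays)
    n_scans <- ceiling((max(stimuli$onset + stimuli$duration) +
                          max(delays)) / tr) + 2L
    binned <- bin_words_to_scans(Fx, stimuli$onset, tr, n_scans)
    drive <- matrix(0, n_scans, o)
    for (k in seq_along(delays)) {
      if (w[k] == 0) next
      lag <- as.integer(round(delays[k] / tr))
      drive[(lag + 1):n_scans, ] <- drive[(lag + 1):n_scans, ] +
        w[k] * binned[1:(n_scans - lag), ]
    }
    signal <- drive %*% G
    sd_sig <- apply(signal, 2, sd)
    base_sd <- mean(sd_sig[responsive])
    noise_sd <- ifelse(responsive, sd_sig / sqrt(snr), base_sd)
    if (!is.finite(snr)) noise_sd <- rep(0, n_channels)
    shared <- colour_noise(with_seed(seed + 555L,
                                     matrix(rnorm(n_scans * n_channels),
                                            n_scans, n_channels)))
    recordings <- lapply(seq_len(n_subjects), function(s) {
      own <- colour_noise(with_seed(seed + 1000L + s,
                                    matrix(rnorm(n_scans * n_channels),
                                           n_scans, n_channels)))
      eps <- sqrt(shared_noise_fraction) * shared +
        sqrt(1 - shared_noise_fraction) * own
      # standardize the realized noise so the variance ratio is exact
      eps <- sweep(eps, 2, apply(eps, 2, sd), `/`)
      brain_recording(s, "fmri", signal + eps %*% diag(noise_sd, n_channels),
                      tr = tr)
    })
    truth <- ground_truth(G = G, responsive = responsive, kernel = kernel,
                          fir_weights = w, delays = delays, snr = snr,
                          noise_sd = noise_sd, signal = signal,
                          shared_noise_fraction = shared_noise_fraction,
                          modality = "fmri", seed = seed)
  } else {
    kernel <- kernel %||% list(latency = 0.4, width = 0.12)
    k <- meg_kernel(kernel, times)
    proj <- Fx %*% G                        # words x channels
    n_words <- nrow(Fx)
    n_times <- length(times)
    signal <- array(0, dim = c(n_words, n_channels, n_times))
    for (t in seq_len(n_times)) signal[, , t] <- proj * k[t]
    sd_sig <- apply(proj, 2, sd)            # per-channel sd at kernel peak
    base_sd <- mean(sd_sig[responsive])
    noise_sd <- ifelse(responsive, sd_sig / sqrt(snr), base_sd)
    if (!is.finite(snr)) noise_sd <- rep(0, n_channels)
    shared <- with_seed(seed + 555L,
                        array(rnorm(n_words * n_channels * n_times),
                              dim = c(n_words, n_channels, n_times)))
    recordings <- lapply(seq_len(n_subjects), function(s) {
      own <- with_seed(seed + 1000L + s,
                       array(rnorm(n_words * n_channels * n_times),
                             dim = c(n_words, n_channels, n_times)))
      eps <- sqrt(shared_noise_fraction) * shared +
        sqrt(1 - shared_noise_fraction) * own
      # standardize the realized noise per channel and time sample so the
      # requested variance ratio is achieved exactly
      eps <- sweep(eps, c(2, 3), apply(eps, c(2, 3), sd), `/`)
      scaled <- sweep(eps, 2, noise_sd, `*`)
      brain_recording(s, "meg", signal + scaled, times = times)
    })
    truth <- ground_truth(G = G, responsive = responsive, kernel = kernel,
                          kernel_curve = k, times = times, snr = snr,
                          noise_sd = noise_sd, signal_peak = proj,
                          shared_noise_fraction = shared_noise_fraction,
                          modality = "meg", seed = seed)
  }
  list(recordings = recordings, truth = truth)
}
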