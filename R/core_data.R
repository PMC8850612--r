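#' @importFrom stats cor sd quantile rnorm rgamma runif wilcox.test p.adjust
#'   median setNames complete.cases binom.test
#' @importFrom utils read.delim head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

required_stimulus_cols <- c("word_id", "token", "onset", "duration",
                            "sentence_id", "block_id", "run_id")

#' Construct a stimulus set
#'
#' A stimulus set is the word-by-word description of a reading experiment:
#' one row per presented word, with its onset and duration (seconds from run
#' start), the sentence it belongs to, the block of consecutive sentences
#' used as the cross-validation unit, and which subjects saw the sentence.
#'
#' @param words A data frame with columns `word_id` (0-based integer index),
#'   `token` (character), `onset`, `duration` (seconds), `sentence_id`,
#'   `block_id`, `run_id` (integers), and optionally `subjects` (a list
#'   column of integer subject ids per word, constant within a sentence).
#' @param min_words,max_words Allowed words-per-sentence range. Generated
#'   stimuli follow the protocol default of 9--15 words; the constructor is
#'   permissive so that toy sets can be built directly.
#' @param block_size Maximum number of sentences per block (default 5).
#' @return A `stimulus_set`: a tibble with the validated columns.
#' @export
stimulus_set <- function(words, min_words = 1L, max_words = Inf,
                         block_size = 5L) {
  missing_cols <- setdiff(required_stimulus_cols, names(words))
  if (length(missing_cols) > 0) {
    stop("stimulus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  words <- tibble::as_tibble(words)
  if (!"subjects" %in% names(words)) {
    words$subjects <- rep(list(0L), nrow(words))
  }
  # onsets strictly increase within each run
  for (r in unique(words$run_id)) {
    idx <- which(words$run_id == r)
    on <- words$onset[idx]
    bad <- which(diff(on) <= 0)
    if (length(bad) > 0) {
      stop(sprintf(
        "stimulus schema error: non-monotone onset at row %d (run %s)",
        idx[bad[1] + 1L], r), call. = FALSE)
    }
  }
  n_per_sentence <- table(words$sentence_id)
  if (any(n_per_sentence < min_words) || any(n_per_sentence > max_words)) {
    off <- names(n_per_sentence)[n_per_sentence < min_words |
                                   n_per_sentence > max_words][1]
    stop(sprintf(
      "stimulus schema error: sentence %s has %d words (allowed %s-%s)",
      off, n_per_sentence[[off]], format(min_words), format(max_words)),
      call. = FALSE)
  }
  # blocks partition sentences, are contiguous and hold <= block_size sentences
  sent <- words[!duplicated(words$sentence_id), c("sentence_id", "block_id")]
  per_block <- table(sent$block_id)
  if (any(per_block > block_size)) {
    stop(sprintf("stimulus schema error: block %s holds %d sentences (max %d)",
                 names(per_block)[which.max(per_block)], max(per_block),
                 block_size), call. = FALSE)
  }
  if (any(tapply(seq_len(nrow(words)), words$block_id,
                 function(i) any(diff(i) != 1L)))) {
    stop("stimulus schema error: block membership not contiguous",
         call. = FALSE)
  }
  class(words) <- c("stimulus_set", class(words))
  words
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d words, %d sentences, %d blocks, %d run(s)\n",
              nrow(x), length(unique(x$sentence_id)),
              length(unique(x$block_id)), length(unique(x$run_id))))
  NextMethod()
}

#' Read / write stimulus metadata as TSV
#'
#' The on-disk format is a tab-separated table with one row per word; the
#' per-sentence subject assignment is serialized in a `subjects` column as a
#' comma-separated list of subject ids. Numeric columns are written at full
#' double precision so a write/read round trip reproduces the stimulus set
#' exactly.
#'
#' @param path Path of the TSV file.
#' @param ... Passed on to [stimulus_set()] (validation bounds).
#' @return `read_stimuli()` returns a validated [stimulus_set()];
#'   `write_stimuli()` returns `path` invisibly.
#' @export
read_stimuli <- function(path, ...) {
  if (!file.exists(path)) stop("stimulus file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(required_stimulus_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("stimulus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  words <- tibble::tibble(
    word_id = as.integer(tab$word_id),
    token = tab$token,
    onset = as.numeric(tab$onset),
    duration = as.numeric(tab$duration),
    sentence_id = as.integer(tab$sentence_id),
    block_id = as.integer(tab$block_id),
    run_id = as.integer(tab$run_id))
  if ("subjects" %in% names(tab)) {
    words$subjects <- lapply(strsplit(tab$subjects, ",", fixed = TRUE),
                             function(s) as.integer(s[nzchar(s)]))
  }
  stimulus_set(words, ...)
}

#' @rdname read_stimuli
#' @param stimuli A [stimulus_set()].
#' @export
write_stimuli <- function(stimuli, path) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  out <- as.data.frame(stimuli[required_stimulus_cols])
  out$onset <- sprintf("%.17g", out$onset)
  out$duration <- sprintf("%.17g", out$duration)
  out$subjects <- vapply(stimuli$subjects, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Model card: provenance of an embedding
#'
#' Records the architecture and training properties of the network an
#' embedding was extracted from, plus where in the stack it sits. These are
#' the covariates of the feature-importance analysis: training task, number
#' of attention heads, number of (contextual) layers, dimensionality,
#' training step, top-1 word-prediction accuracy, and relative layer
#' position.
#'
#' Layer convention: `n_layers` counts the contextual layers; the full stack
#' additionally holds one non-contextual word-embedding layer at
#' `layer_index = 0`, so indices run 0..`n_layers` and
#' `layer_position = layer_index / n_layers` (0 for the word-embedding
#' layer, 1 for the last contextual layer).
#'
#' @param task `"causal"` (predict the next word), `"masked"` (predict a
#'   masked word), or `"visual"` for the character-recognition stand-in.
#' @param n_layers Number of contextual layers (>= 1).
#' @param dim Embedding dimensionality.
#' @param n_heads Number of attention heads.
#' @param training_step Number of gradient updates (>= 0).
#' @param accuracy_top1 Top-1 word-prediction accuracy in \[0, 1\].
#' @param layer_index Integer in 0..`n_layers`; 0 is the word-embedding layer.
#' @return A `model_card` list.
#' @export
model_card <- function(task, n_layers, dim, n_heads, training_step,
                       accuracy_top1, layer_index) {
  task <- match.arg(task, c("causal", "masked", "visual"))
  n_layers <- as.integer(n_layers)
  layer_index <- as.integer(layer_index)
  if (n_layers < 1L) stop("n_layers must be >= 1", call. = FALSE)
  if (layer_index < 0L || layer_index > n_layers) {
    stop("layer_index must lie in 0..n_layers", call. = FALSE)
  }
  if (accuracy_top1 < 0 || accuracy_top1 > 1) {
    stop("accuracy_top1 must lie in [0, 1]", call. = FALSE)
  }
  if (training_step < 0) stop("training_step must be >= 0", call. = FALSE)
  structure(list(
    task = task, n_layers = n_layers, dim = as.integer(dim),
    n_heads = as.integer(n_heads), training_step = as.numeric(training_step),
    accuracy_top1 = as.numeric(accuracy_top1), layer_index = layer_index,
    layer_position = layer_index / n_layers),
    class = "model_card")
}

#' @export
print.model_card <- function(x, ...) {
  cat(sprintf(
    "<model_card> %s, %d layers x %d dim, %d heads, step %g, acc %.3f, layer %d (pos %.2f)\n",
    x$task, x$n_layers, x$dim, x$n_heads, x$training_step, x$accuracy_top1,
    x$layer_index, x$layer_position))
  invisible(x)
}

#' Embedding matrix aligned to a stimulus set
#'
#' Holds one activation vector per word (rows) for a given layer of a given
#' model, together with the word ids it is aligned to and the model card
#' describing its provenance. This is the design matrix X of the encoding
#' model.
#'
#' @param values Numeric matrix, words x dimensions; all values finite.
#' @param word_ids Integer vector aligning rows to `stimulus_set$word_id`.
#' @param card A [model_card()].
#' @return An `embedding_matrix` (a matrix with attributes).
#' @export
embedding_matrix <- function(values, word_ids, card) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("embedding values must be finite numerics", call. = FALSE)
  }
  if (nrow(values) != length(word_ids)) {
    stop(sprintf("alignment error: %d embedding rows vs %d word ids",
                 nrow(values), length(word_ids)), call. = FALSE)
  }
  stopifnot(inherits(card, "model_card"))
  structure(values, word_ids = as.integer(word_ids), card = card,
            class = c("embedding_matrix", "matrix", "array"))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d words x %d dims\n", nrow(x), ncol(x)))
  print(attr(x, "card"))
  invisible(x)
}

#' Check that an embedding is aligned with a stimulus set
#' @param embedding An [embedding_matrix()].
#' @param stimuli A [stimulus_set()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_alignment <- function(embedding, stimuli) {
  ids <- attr(embedding, "word_ids")
  if (length(ids) != nrow(stimuli) || any(ids != stimuli$word_id)) {
    stop(sprintf("alignment error: embedding rows (%d) do not match stimulus words (%d)",
                 length(ids), nrow(stimuli)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Brain recording for one subject
#'
#' Two modalities are supported. In fMRI mode, responses live on the scanner
#' time grid: a scans x voxels matrix with a repetition time `tr` and scan
#' onset times. In MEG mode, responses are word-locked epochs: a
#' words x channels x times array whose time axis covers word onset at t = 0
#' (default epoch \eqn{-0.5 \ldots +2.0} s).
#'
#' @param subject_id Integer subject identifier.
#' @param modality `"fmri"` or `"meg"`.
#' @param data Matrix (fmri: scans x voxels) or 3-d array
#'   (meg: words x channels x times).
#' @param tr Repetition time in seconds (fmri).
#' @param scan_onsets Scan onset times in seconds (fmri); defaults to
#'   `(0:(n_scans-1)) * tr`.
#' @param times Epoch time axis in seconds (meg).
#' @param labels Channel / voxel labels.
#' @return A `brain_recording` list.
#' @export
brain_recording <- function(subject_id, modality = c("fmri", "meg"), data,
                            tr = NULL, scan_onsets = NULL, times = NULL,
                            labels = NULL) {
  modality <- match.arg(modality)
  if (modality == "fmri") {
    data <- as.matrix(data)
    if (is.null(tr)) stop("fmri recording needs a tr", call. = FALSE)
    if (is.null(scan_onsets)) scan_onsets <- (seq_len(nrow(data)) - 1) * tr
    if (length(scan_onsets) != nrow(data)) {
      stop("shape error: scan_onsets length must equal number of scans",
           call. = FALSE)
    }
    labels <- labels %||% paste0("v", seq_len(ncol(data)))
  } else {
    if (length(dim(data)) != 3) {
      stop("shape error: meg data must be a words x channels x times array",
           call. = FALSE)
    }
    times <- times %||% seq(-0.5, 2.0, length.out = dim(data)[3])
    if (length(times) != dim(data)[3]) {
      stop("shape error: time axis length does not match the epoch array",
           call. = FALSE)
    }
    if (min(times) > 0 || max(times) < 0) {
      stop("meg epoch axis must cover word onset at t = 0", call. = FALSE)
    }
    labels <- labels %||% paste0("ch", seq_len(dim(data)[2]))
  }
  structure(list(subject_id = as.integer(subject_id), modality = modality,
                 data = data, tr = tr, scan_onsets = scan_onsets,
                 times = times, labels = labels),
            class = "brain_recording")
}

#' @export
print.brain_recording <- function(x, ...) {
  if (x$modality == "fmri") {
    cat(sprintf("<brain_recording> subject %d, fmri: %d scans x %d voxels (TR %gs)\n",
                x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  } else {
    d <- dim(x$data)
    cat(sprintf("<brain_recording> subject %d, meg: %d words x %d channels x %d times\n",
                x$subject_id, d[1], d[2], d[3]))
  }
  invisible(x)
}

#' Linear projection operator (e.g. sensor-to-source)
#'
#' A matrix K (m sources x n sensors) applied to both the observed and the
#' predicted responses before correlation, as when MEG sensor predictions
#' are evaluated in source space.
#'
#' @param K Numeric matrix, sources x sensors.
#' @param labels Optional source labels.
#' @return A `projection_operator`.
#' @export
projection_operator <- function(K, labels = NULL) {
  K <- as.matrix(K)
  structure(list(K = K, labels = labels %||% paste0("src", seq_len(nrow(K)))),
            class = "projection_operator")
}

#' Brain-score map for one subject
#'
#' Per-target cross-validated Pearson correlations ("brain scores"): a
#' vector over voxels (fmri) or a channels x times matrix (meg), together
#' with the model card of the embedding that produced them, the
#' cross-validation fold assignment, and a flag marking degenerate
#' (zero-variance) targets whose score is fixed at 0.
#'
#' @param subject_id Integer subject id.
#' @param scores Numeric vector or matrix of Pearson R in \[-1, 1\].
#' @param card The generating [model_card()].
#' @param folds Block-to-fold assignment used for cross-validation.
#' @param degenerate Logical, same shape as `scores`.
#' @return A `score_map`.
#' @export
score_map <- function(subject_id, scores, card, folds = NULL,
                      degenerate = NULL) {
  if (is.null(degenerate)) {
    degenerate <- array(FALSE, dim = dim(scores) %||% length(scores))
  }
  ok <- degenerate | (scores >= -1 - 1e-12 & scores <= 1 + 1e-12)
  if (!all(ok)) stop("scores outside [-1, 1] and not flagged degenerate",
                     call. = FALSE)
  structure(list(subject_id = as.integer(subject_id), scores = scores,
                 card = card, folds = folds, degenerate = degenerate),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> subject %d, %s targets, mean R = %.4f\n",
              x$subject_id, paste(dim(x$scores) %||% length(x$scores),
                                  collapse = " x "),
              mean(x$scores[!x$degenerate])))
  invisible(x)
}

## ---- array container (TSV values + JSON metadata sidecar) ----

fmt_matrix <- function(m) {
  apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
}

write_values_tsv <- function(m, path) {
  writeLines(fmt_matrix(m), path)
  invisible(path)
}

read_values_tsv <- function(path, ncol) {
  v <- scan(path, what = double(), sep = "\t", quiet = TRUE)
  matrix(v, ncol = ncol, byrow = TRUE)
}

card_to_list <- function(card) unclass(card)

card_from_list <- function(l) {
  model_card(l$task, l$n_layers, l$dim, l$n_heads, l$training_step,
             l$accuracy_top1, l$layer_index)
}

#' Write / read numeric array containers
#'
#' Arrays ([embedding_matrix()] and [brain_recording()]) are stored as a
#' pair of plain-text files: `<path>.tsv` holding the values at full double
#' precision (17 significant digits, so round trips are bit-identical) and
#' `<path>.json` holding shape and metadata. MEG epoch arrays are flattened
#' to words x (channels * times) with dimensions recorded in the sidecar.
#'
#' @param x An `embedding_matrix` or `brain_recording`.
#' @param path Path prefix (without extension).
#' @return `write_arrays()` returns `path` invisibly; `read_arrays()`
#'   returns the reconstructed object.
#' @export
write_arrays <- function(x, path) {
  if (inherits(x, "embedding_matrix")) {
    meta <- list(kind = "embedding", n_row = nrow(x), n_col = ncol(x),
                 word_ids = attr(x, "word_ids"),
                 card = card_to_list(attr(x, "card")))
    write_values_tsv(unclass(x), paste0(path, ".tsv"))
  } else if (inherits(x, "brain_recording")) {
    if (x$modality == "fmri") {
      meta <- list(kind = "brain", modality = "fmri",
                   subject_id = x$subject_id, n_row = nrow(x$data),
                   n_col = ncol(x$data), tr = x$tr,
                   scan_onsets = sprintf("%.17g", x$scan_onsets),
                   labels = x$labels)
      write_values_tsv(x$data, paste0(path, ".tsv"))
    } else {
      d <- dim(x$data)
      meta <- list(kind = "brain", modality = "meg",
                   subject_id = x$subject_id, dims = d,
                   times = sprintf("%.17g", x$times), labels = x$labels)
      write_values_tsv(matrix(x$data, nrow = d[1]), paste0(path, ".tsv"))
    }
  } else if (inherits(x, "score_map")) {
    sc <- as.matrix(x$scores)
    meta <- list(kind = "scores", subject_id = x$subject_id,
                 n_row = nrow(sc), n_col = ncol(sc),
                 degenerate = as.integer(x$degenerate),
                 folds = as.list(x$folds), card = card_to_list(x$card))
    write_values_tsv(sc, paste0(path, ".tsv"))
  } else {
    stop("write_arrays supports embedding_matrix, brain_recording and score_map objects",
         call. = FALSE)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_arrays
#' @export
read_arrays <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (meta$kind == "embedding") {
    vals <- read_values_tsv(paste0(path, ".tsv"), meta$n_col)
    embedding_matrix(vals, meta$word_ids, card_from_list(as.list(meta$card)))
  } else if (meta$kind == "scores") {
    sc <- read_values_tsv(paste0(path, ".tsv"), meta$n_col)
    folds <- unlist(meta$folds)
    score_map(meta$subject_id, sc, card_from_list(as.list(meta$card)),
              folds = folds,
              degenerate = array(meta$degenerate == 1L, dim = dim(sc)))
  } else if (meta$modality == "fmri") {
    vals <- read_values_tsv(paste0(path, ".tsv"), meta$n_col)
    brain_recording(meta$subject_id, "fmri", vals, tr = meta$tr,
                    scan_onsets = as.numeric(meta$scan_onsets),
                    labels = meta$labels)
  } else {
    d <- meta$dims
    flat <- read_values_tsv(paste0(path, ".tsv"), d[2] * d[3])
    brain_recording(meta$subject_id, "meg", array(flat, dim = d),
                    times = as.numeric(meta$times), labels = meta$labels)
  }
}

## seeded RNG scoped to a block, leaving the global stream untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## deterministic 31-bit string hash (for token -> seed lookups)
string_hash <- function(s, seed = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}
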