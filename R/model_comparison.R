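#' Gain of one embedding over another
#'
#' The elementwise difference of brain scores \eqn{\Delta R = R_{M1} -
#' R_{M2}} between two embeddings evaluated on the same subject and target
#' grid — the quantity used to attribute signal to a representation level
#' (e.g. compositional over lexical). Exactly linear: antisymmetric in its
#' arguments and additive along chains.
#'
#' @param score_m1,score_m2 Two [score_map()]s for the same subject and
#'   target grid.
#' @return A `gain_map`: `$delta` (same shape as the scores),
#'   `$degenerate` (union of both flags), `$subject_id`, `$card_m1`,
#'   `$card_m2`.
#' @export
gain <- function(score_m1, score_m2) {
  stopifnot(inherits(score_m1, "score_map"), inherits(score_m2, "score_map"))
  if (score_m1$subject_id != score_m2$subject_id) {
    stop("gain requires score maps from the same subject", call. = FALSE)
  }
  if (!identical(dim(score_m1$scores) %||% length(score_m1$scores),
                 dim(score_m2$scores) %||% length(score_m2$scores))) {
    stop("gain requires score maps on the same target grid", call. = FALSE)
  }
  structure(list(delta = score_m1$scores - score_m2$scores,
                 degenerate = score_m1$degenerate | score_m2$degenerate,
                 subject_id = score_m1$subject_id,
                 card_m1 = score_m1$card, card_m2 = score_m2$card),
            class = "gain_map")
}

#' Spatially (and temporally) averaged score
#'
#' Collapses a score map (or gain map) to one scalar per subject: the mean
#' over voxels, or over channels and time samples for MEG, honouring the
#' degenerate flags (flagged targets are excluded from the mean). For MEG
#' the average can be restricted to a channel mask and/or to the
#' 10-sample subsampled time axis used for model comparison.
#'
#' @param smap A [score_map()] or [gain()] result.
#' @param mask Optional logical mask over targets (vector over voxels or
#'   channels, or the full score shape). Must select at least one
#'   non-degenerate target.
#' @param time_indices Optional time-axis restriction for MEG maps (see
#'   [meg_time_subsample()]).
#' @return A single numeric mean score.
#' @export
average_scores <- function(smap, mask = NULL, time_indices = NULL) {
  scores <- if (inherits(smap, "gain_map")) smap$delta else smap$scores
  degenerate <- smap$degenerate
  keep <- !degenerate
  if (!is.null(mask)) {
    if (is.matrix(scores) && !is.matrix(mask)) {
      mask <- matrix(mask, nrow(scores), ncol(scores))
    }
    keep <- keep & mask
  }
  if (!is.null(time_indices) && is.matrix(scores)) {
    tm <- matrix(FALSE, nrow(scores), ncol(scores))
    tm[, time_indices] <- TRUE
    keep <- keep & tm
  }
  if (!any(keep)) stop("average_scores: empty mask", call. = FALSE)
  mean(scores[keep])
}

#' Comparison table across embeddings and subjects
#'
#' One row per (embedding, subject): the model-card properties of the
#' embedding and the subject's spatially/temporally averaged brain score.
#' The averaging specification is recorded as an attribute.
#'
#' @param score_maps A list of [score_map()]s (any mix of subjects and
#'   embeddings).
#' @param mask,time_indices Passed to [average_scores()].
#' @return A tibble with columns `subject`, the card fields, and `score`;
#'   attribute `"averaging"` records the averaging settings.
#' @export
comparison_table <- function(score_maps, mask = NULL, time_indices = NULL) {
  rows <- lapply(score_maps, function(sm) {
    cd <- sm$card
    tibble::tibble(
      subject = sm$subject_id, task = cd$task, n_heads = cd$n_heads,
      n_layers = cd$n_layers, dim = cd$dim,
      training_step = cd$training_step, accuracy_top1 = cd$accuracy_top1,
      layer_index = cd$layer_index, layer_position = cd$layer_position,
      score = average_scores(sm, mask = mask, time_indices = time_indices))
  })
  out <- do.call(rbind, rows)
  attr(out, "averaging") <- list(mask = !is.null(mask),
                                 time_indices = time_indices)
  out
}

#' Convergence of a model family towards brain-like representations
#'
#' For each subject, the Pearson correlation between the average brain
#' score of every network checkpoint and either its word-prediction
#' accuracy or its training step. Positive correlations indicate
#' convergence (better language models map better onto the brain),
#' negative ones divergence.
#'
#' @param table A [comparison_table()].
#' @param key `"accuracy_top1"` or `"training_step"`.
#' @return A tibble with one row per subject: `subject`, `r`, and a
#'   `degenerate` flag (constant scores or key; `r` is 0 there, not NaN).
#' @export
convergence <- function(table, key = c("accuracy_top1", "training_step")) {
  key <- match.arg(key)
  subjects <- unique(table$subject)
  rows <- lapply(subjects, function(s) {
    sub <- table[table$subject == s, ]
    degenerate <- sd(sub$score) == 0 || sd(sub[[key]]) == 0 || nrow(sub) < 3
    r <- if (degenerate) 0 else cor(sub$score, sub[[key]])
    tibble::tibble(subject = s, r = r, degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Layer profile of brain scores across depth
#'
#' Mean score per layer index (across subjects and checkpoints), the
#' best-scoring layer, and whether it falls in the middle-layer band
#' \[n/2, 3n/4\] where the inverted-U profile of transformer depth peaks.
#'
#' @param table A [comparison_table()].
#' @return A list: `$profile` (tibble `layer_index`, `layer_position`,
#'   `mean_score`), `$best_layer`, `$in_middle`.
#' @export
layer_profile <- function(table) {
  layers <- sort(unique(table$layer_index))
  prof <- do.call(rbind, lapply(layers, function(l) {
    sub <- table[table$layer_index == l, ]
    tibble::tibble(layer_index = l,
                   layer_position = sub$layer_position[1],
                   mean_score = mean(sub$score))
  }))
  best <- prof$layer_index[which.max(prof$mean_score)]
  n_layers <- table$n_layers[1]
  in_middle <- if (n_layers >= 2) best %in% middle_layers(n_layers) else NA
  list(profile = prof, best_layer = best, in_middle = in_middle)
}

#' Residualize one embedding against another
#'
#' Optional orthogonalization mode for level comparisons: returns M1 with
#' the column space of M2 regressed out (ordinary least squares), so that
#' gains can be computed against a lower-level representation's unique
#' contribution. Not applied by default — the standard comparison is the
#' raw score difference.
#'
#' @param m1,m2 Two [embedding_matrix()]s aligned to the same words.
#' @return An [embedding_matrix()] of residuals carrying M1's card.
#' @export
residualize_embedding <- function(m1, m2) {
  stopifnot(identical(attr(m1, "word_ids"), attr(m2, "word_ids")))
  X2 <- cbind(1, unclass(m2))
  beta <- qr.coef(qr(X2), unclass(m1))
  beta[is.na(beta)] <- 0
  embedding_matrix(unclass(m1) - X2 %*% beta, attr(m1, "word_ids"),
                   attr(m1, "card"))
}
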