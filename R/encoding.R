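#' Default ridge regularization grid
#'
#' Twenty values log-spaced between 1e-3 and 1e8, the grid searched by the
#' nested leave-one-out selection in [ridge_fit()].
#'
#' @return Numeric vector of length 20.
#' @export
ridge_lambda_grid <- function() 10^seq(-3, 8, length.out = 20)

#' Feature / response scalers fitted on the training split only
#'
#' `method = "zscore"` standardizes each column to mean 0, sd 1 using
#' training statistics. `method = "robust"` first clips each column at its
#' training 0.01st and 99.99th percentiles, then standardizes with the
#' post-clipping mean and sd; applied data are clipped at the training
#' bounds too. Zero-variance columns are mapped to all zeros and flagged
#' in `$degenerate` instead of producing NaNs.
#'
#' @param X Numeric matrix (samples x dimensions), >= 2 rows.
#' @param method `"zscore"` or `"robust"`.
#' @param clip Clipping quantiles for the robust scaler
#'   (default `c(1e-4, 0.9999)`, i.e. the 0.01st and 99.99th percentiles).
#' @return A `scaler` with `$center`, `$scale`, `$degenerate`, and for the
#'   robust method `$lo`, `$hi`.
#' @export
fit_scaler <- function(X, method = c("zscore", "robust"),
                       clip = c(1e-4, 0.9999)) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("scaler needs >= 2 samples", call. = FALSE)
  n <- nrow(X)
  if (method == "robust") {
    # inverse-ECDF quantiles: the clip bound is an observed value, so one
    # extreme outlier cannot drag the bound toward itself
    k_lo <- max(1L, ceiling(n * clip[1]))
    k_hi <- max(1L, ceiling(n * clip[2]))
    if (k_lo == 1L && k_hi == n) {
      # below ~10^4 samples the clip quantiles are the column extremes
      # (computed through max.col, a single C pass per direction), and
      # clipping the train data itself is a no-op
      tX <- t(X)
      q <- ncol(X)
      hi <- tX[cbind(seq_len(q), max.col(tX, ties.method = "first"))]
      lo <- tX[cbind(seq_len(q), max.col(-tX, ties.method = "first"))]
      Xc <- X
    } else {
      bounds <- apply(X, 2, function(x) {
        s <- sort(x, partial = c(k_lo, k_hi))
        c(s[k_lo], s[k_hi])
      })
      lo <- bounds[1, ]
      hi <- bounds[2, ]
      Xc <- pmin(pmax(X, rep(lo, each = n)), rep(hi, each = n))
    }
  } else {
    lo <- hi <- NULL
    Xc <- X
  }
  ctr <- colMeans(Xc)
  scl <- sqrt(pmax(colSums(Xc^2) - n * ctr^2, 0) / (n - 1))
  degenerate <- scl == 0 | !is.finite(scl)
  scl[degenerate] <- 1
  clip_noop <- method != "robust" ||
    (max(1L, ceiling(n * clip[1])) == 1L && max(1L, ceiling(n * clip[2])) == n)
  structure(list(method = method, center = ctr, scale = scl, lo = lo,
                 hi = hi, degenerate = degenerate, clip_noop = clip_noop),
            class = "scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$center)) {
    stop("scaler dimensionality mismatch", call. = FALSE)
  }
  if (scaler$method == "robust") {
    X <- pmin(pmax(X, rep(scaler$lo, each = nrow(X))),
              rep(scaler$hi, each = nrow(X)))
  }
  out <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
  out[, scaler$degenerate] <- 0
  out
}

# center/scale without the clip step (exact for data the bounds were fit on)
standardize_only <- function(scaler, X) {
  out <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
  out[, scaler$degenerate] <- 0
  out
}

#' Ridge regression with per-target leave-one-out lambda selection
#'
#' Solves \eqn{W = (X^T X + \lambda I)^{-1} X^T Y} for every target column
#' of Y, selecting \eqn{\lambda} for each target independently from the
#' grid by minimizing the exact leave-one-out prediction error on the
#' training split. The LOO curve is computed in closed form from one SVD
#' of X (residuals divided by \eqn{1 - h_{ii}}, the ridge leverage), which
#' is algebraically identical to refitting with each sample held out.
#'
#' @param X Training design matrix (samples x features), finite.
#' @param Y Training responses (samples x targets), finite.
#' @param lambdas Candidate grid (default [ridge_lambda_grid()]). Ties in
#'   the LOO error pick the smallest lambda.
#' @return A `ridge_fit`: `$W` (features x targets), `$lambda` (selected
#'   value per target), `$lambdas`, and `$press` (the LOO
#'   sum-of-squared-errors curve, grid x targets).
#' @export
ridge_fit <- function(X, Y, lambdas = ridge_lambda_grid()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2) stop("ridge_fit needs at least 2 training samples",
                        call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("ridge_fit requires finite inputs", call. = FALSE)
  }
  sv <- svd(X)
  d2 <- sv$d^2
  A <- crossprod(sv$u, Y)                  # r x q
  U2 <- sv$u^2
  q <- ncol(Y)
  Y2 <- Y^2
  press <- matrix(NA_real_, length(lambdas), q)
  # LOO residual e_i = (y_i - yhat_i) / (1 - h_i) with h = U2 f; the PRESS
  # column sums are expanded into quadratic forms so the n x q work is one
  # BLAS product per lambda:
  #   sum_i w_i^2 (y_ij - sum_k f_k u_ik a_kj)^2
  #     = y'W2y - 2 (fA)'U'W2y + (fA)'U'W2U(fA),   w = 1/(1-h), W2 = diag(w^2)
  for (j in seq_along(lambdas)) {
    f <- d2 / (d2 + lambdas[j])
    w2 <- 1 / (1 - as.numeric(U2 %*% f))^2
    Uw <- sv$u * w2
    fA <- f * A
    t1 <- as.numeric(crossprod(Y2, w2))
    t2 <- colSums(fA * crossprod(Uw, Y))
    t3 <- colSums(fA * (crossprod(sv$u, Uw) %*% fA))
    press[j, ] <- t1 - 2 * t2 + t3
  }
  best <- apply(press, 2, which.min)
  W <- matrix(0, ncol(X), q)
  for (j in unique(best)) {
    cols <- which(best == j)
    g <- sv$d / (d2 + lambdas[j])
    W[, cols] <- sv$v %*% (g * A[, cols, drop = FALSE])
  }
  structure(list(W = W, lambda = lambdas[best], lambdas = lambdas,
                 press = press, n_train = nrow(X)), class = "ridge_fit")
}

#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$W
}

#' Per-target Pearson correlation score
#'
#' The evaluation metric of the encoding model: Pearson R between observed
#' and predicted responses, computed per target dimension on the held-out
#' split. A zero-variance column in either argument scores 0 and is
#' flagged degenerate (attribute `"degenerate"`) rather than NaN.
#'
#' @param Y,Yhat Matrices (samples x targets) of observed and predicted
#'   responses.
#' @return Numeric vector of R per target, with a logical `"degenerate"`
#'   attribute.
#' @export
pearson_score <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  stopifnot(dim(Y) == dim(Yhat))
  Yc <- sweep(Y, 2, colMeans(Y))
  Pc <- sweep(Yhat, 2, colMeans(Yhat))
  sy <- sqrt(colSums(Yc^2))
  sp <- sqrt(colSums(Pc^2))
  degenerate <- sy == 0 | sp == 0
  r <- colSums(Yc * Pc) / (sy * sp)
  r[degenerate] <- 0
  r <- pmin(1, pmax(-1, r))
  attr(r, "degenerate") <- degenerate
  r
}

#' Sum word-level features into scanner time bins
#'
#' @param X Word-level feature matrix (words x features).
#' @param onsets Word onsets in seconds.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans on the grid.
#' @return Matrix scans x features; bin b covers `[(b-1) * tr, b * tr)`.
#' @export
bin_words_to_scans <- function(X, onsets, tr, n_scans) {
  bins <- floor(onsets / tr) + 1L
  if (any(bins > n_scans) || any(bins < 1L)) {
    stop("word onset falls outside the scan grid", call. = FALSE)
  }
  out <- matrix(0, n_scans, ncol(X))
  agg <- rowsum(as.matrix(X), bins)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Finite impulse response expansion of a word-level design matrix
#'
#' Builds the scan-grid design matrix X* from word-level features X: word
#' rows are summed into the TR bin containing their onset, and X* stacks
#' one delayed copy of the binned matrix per FIR delay (columns =
#' features x delays). Scans preceding the first valid delay contain
#' zeros. This captures the hemodynamic lag without assuming a response
#' shape.
#'
#' @param X Word-level features (words x o).
#' @param onsets Word onsets, seconds.
#' @param tr Repetition time (default 2 s).
#' @param delays FIR delays in seconds (default 2, 4, 6, 8, 10).
#' @param n_scans Scans on the grid; default covers the last onset plus
#'   the largest delay.
#' @param nearest_bin If TRUE, delays that are not multiples of `tr` are
#'   rounded to the nearest scan with a warning; otherwise they are a
#'   configuration error.
#' @return Matrix `n_scans x (o * length(delays))`; columns are grouped by
#'   delay (all features at delay 1, then delay 2, ...).
#' @export
fir_expand <- function(X, onsets, tr = 2, delays = c(2, 4, 6, 8, 10),
                       n_scans = NULL, nearest_bin = FALSE) {
  X <- as.matrix(X)
  lag_exact <- delays / tr
  lags <- round(lag_exact)
  if (any(abs(lag_exact - lags) > 1e-9)) {
    if (!nearest_bin) {
      stop("config error: FIR delay not a multiple of TR", call. = FALSE)
    }
    warning("FIR delay rounded to the nearest scan bin")
  }
  n_scans <- n_scans %||% (floor(max(onsets) / tr) + 1L + max(lags))
  binned <- bin_words_to_scans(X, onsets, tr, n_scans)
  o <- ncol(X)
  out <- matrix(0, n_scans, o * length(delays))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    rows <- seq_len(n_scans - lag)
    out[rows + lag, (k - 1L) * o + seq_len(o)] <- binned[rows, , drop = FALSE]
  }
  out
}

#' Blocked cross-validation scheme
#'
#' Folds are assigned at the level of 5-sentence blocks so that no block
#' ever spans the train and test sets — the leakage control of the whole
#' pipeline.
#'
#' @param stimuli A [stimulus_set()].
#' @param n_folds Number of folds (default 5).
#' @param seed Optional seed shuffling blocks before round-robin
#'   assignment; `NULL` keeps presentation order.
#' @return A `cv_scheme`: `$folds` (named integer vector, block id ->
#'   fold) and `$n_folds`.
#' @export
cv_scheme <- function(stimuli, n_folds = 5L, seed = NULL) {
  blocks <- unique(stimuli$block_id)
  if (length(blocks) < n_folds) {
    stop(sprintf("CV error: %d blocks cannot fill %d folds", length(blocks),
                 n_folds), call. = FALSE)
  }
  if (!is.null(seed)) blocks <- with_seed(seed, sample(blocks))
  folds <- setNames(rep(seq_len(n_folds), length.out = length(blocks)),
                    blocks)
  structure(list(folds = folds, n_folds = as.integer(n_folds)),
            class = "cv_scheme")
}

fold_blocks <- function(cv, fold, test = TRUE) {
  ids <- as.integer(names(cv$folds))
  if (test) ids[cv$folds == fold] else ids[cv$folds != fold]
}

assert_disjoint <- function(train_idx, test_idx) {
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("leakage: train and test sets overlap", call. = FALSE)
  }
  if (length(train_idx) < 2 || length(test_idx) < 1) {
    stop("CV error: empty or undersized train/test split", call. = FALSE)
  }
  invisible(TRUE)
}

## per scan: which blocks contribute any (FIR-delayed) signal
scan_block_sets <- function(stimuli, tr, delays, n_scans) {
  lags <- round(delays / tr)
  bins <- floor(stimuli$onset / tr) + 1L
  scan <- rep(bins, each = length(lags)) + rep(lags, length(bins))
  block <- rep(stimuli$block_id, each = length(lags))
  keep <- scan >= 1 & scan <= n_scans
  tapply(block[keep], factor(scan[keep], levels = seq_len(n_scans)),
         unique, default = integer(0))
}

scans_for_blocks <- function(scan_sets, blocks, all_blocks) {
  other <- setdiff(all_blocks, blocks)
  which(vapply(scan_sets, function(s) {
    length(s) > 0 && all(s %in% blocks) && !any(s %in% other)
  }, TRUE))
}

average_fold_scores <- function(per_fold_scores, per_fold_degenerate) {
  scores <- Reduce(`+`, per_fold_scores) / length(per_fold_scores)
  degenerate <- Reduce(`|`, per_fold_degenerate)
  scores[degenerate] <- 0
  list(scores = scores, degenerate = degenerate)
}

#' fMRI brain score of an embedding
#'
#' For each cross-validation fold: the embedding is standardized across
#' training words, expanded with the FIR model onto the scan grid, and a
#' ridge mapping with per-voxel leave-one-out lambda selection is fitted on
#' the training scans; held-out scans are predicted and scored with a
#' Pearson correlation per voxel. Scores are averaged across folds.
#'
#' A scan enters the test set only if every FIR-delayed contribution it
#' receives comes from test-block words (and conversely for training);
#' scans mixing train and test blocks are dropped — strict leakage control
#' at block seams, asserted as a hard failure.
#'
#' @param embedding An [embedding_matrix()] aligned with `stimuli`.
#' @param recording An fMRI [brain_recording()].
#' @param stimuli The [stimulus_set()].
#' @param cv A [cv_scheme()] (default: 5 folds in presentation order).
#' @param lambdas Ridge grid.
#' @param delays FIR delays, seconds.
#' @return A [score_map()] with one R per voxel.
#' @export
brain_score_fmri <- function(embedding, recording, stimuli,
                             cv = cv_scheme(stimuli),
                             lambdas = ridge_lambda_grid(),
                             delays = c(2, 4, 6, 8, 10)) {
  stopifnot(recording$modality == "fmri")
  check_alignment(embedding, stimuli)
  n_scans <- nrow(recording$data)
  scan_sets <- scan_block_sets(stimuli, recording$tr, delays, n_scans)
  all_blocks <- unique(stimuli$block_id)
  fold_scores <- list(); fold_deg <- list()
  for (f in seq_len(cv$n_folds)) {
    test_blocks <- fold_blocks(cv, f, test = TRUE)
    train_blocks <- fold_blocks(cv, f, test = FALSE)
    train_words <- stimuli$block_id %in% train_blocks
    xsc <- fit_scaler(unclass(embedding)[train_words, , drop = FALSE],
                      "zscore")
    Xs <- apply_scaler(xsc, unclass(embedding))
    Xstar <- fir_expand(Xs, stimuli$onset, recording$tr, delays, n_scans)
    train_scans <- scans_for_blocks(scan_sets, train_blocks, all_blocks)
    test_scans <- scans_for_blocks(scan_sets, test_blocks, all_blocks)
    assert_disjoint(train_scans, test_scans)
    ysc <- fit_scaler(recording$data[train_scans, , drop = FALSE], "robust")
    Ys <- apply_scaler(ysc, recording$data)
    fit <- ridge_fit(Xstar[train_scans, , drop = FALSE],
                     Ys[train_scans, , drop = FALSE], lambdas)
    r <- pearson_score(Ys[test_scans, , drop = FALSE],
                       predict(fit, Xstar[test_scans, , drop = FALSE]))
    fold_scores[[f]] <- as.numeric(r)
    fold_deg[[f]] <- attr(r, "degenerate") | ysc$degenerate
  }
  avg <- average_fold_scores(fold_scores, fold_deg)
  score_map(recording$subject_id, avg$scores, attr(embedding, "card"),
            folds = cv$folds, degenerate = avg$degenerate)
}

#' Indices of a regularly spaced MEG time subsample
#'
#' Picks `n` samples regularly distributed between 0 and 2 s on the epoch
#' axis (nearest grid point each), the convention used when averaging MEG
#' scores for model comparison.
#'
#' @param times Epoch time axis, seconds.
#' @param n Number of samples (default 10).
#' @param range Time window (default `c(0, 2)`).
#' @return Integer indices into `times`.
#' @export
meg_time_subsample <- function(times, n = 10L, range = c(0, 2)) {
  targets <- seq(range[1], range[2], length.out = n)
  unique(vapply(targets, function(t) which.min(abs(times - t)), 1L))
}

#' MEG brain score of an embedding
#'
#' The fMRI pipeline minus the FIR expansion: the mapping is fitted and
#' evaluated at each epoch time sample independently (word epochs are the
#' samples), with the same blocked cross-validation, scaling and ridge
#' machinery. Optionally restricted to a subsampled time axis.
#'
#' @inheritParams brain_score_fmri
#' @param recording An MEG [brain_recording()].
#' @param time_indices Optional integer indices restricting the time axis
#'   (see [meg_time_subsample()]); scores at other samples are 0 and
#'   flagged degenerate.
#' @return A [score_map()] with a channels x times score matrix.
#' @export
brain_score_meg <- function(embedding, recording, stimuli,
                            cv = cv_scheme(stimuli),
                            lambdas = ridge_lambda_grid(),
                            time_indices = NULL) {
  brain_score_meg_group(embedding, list(recording), stimuli, cv = cv,
                        lambdas = lambdas, time_indices = time_indices)[[1]]
}

#' Batched MEG brain scores for several subjects
#'
#' Scores one embedding against the recordings of many subjects in a
#' single pass. Because scaling, per-target lambda selection and the
#' Pearson score are all columnwise-independent, stacking the subjects'
#' channels into one response matrix yields exactly the per-subject
#' results of [brain_score_meg()] (asserted in the test suite), at a
#' fraction of the cost — the design-side work is shared.
#'
#' @inheritParams brain_score_meg
#' @param recordings A list of MEG [brain_recording()]s on the same epoch
#'   grid.
#' @return A list of [score_map()]s, one per recording.
#' @export
brain_score_meg_group <- function(embedding, recordings, stimuli,
                                  cv = cv_scheme(stimuli),
                                  lambdas = ridge_lambda_grid(),
                                  time_indices = NULL) {
  check_alignment(embedding, stimuli)
  d1 <- dim(recordings[[1]]$data)
  for (rec in recordings) {
    stopifnot(rec$modality == "meg")
    if (!identical(dim(rec$data), d1)) {
      stop("shape error: recordings disagree on epoch dimensions",
           call. = FALSE)
    }
  }
  if (d1[1] != nrow(stimuli)) {
    stop("shape error: epoch count does not match stimulus words",
         call. = FALSE)
  }
  n_sub <- length(recordings)
  n_ch <- d1[2]; n_t <- d1[3]
  t_idx <- time_indices %||% seq_len(n_t)
  # slice and stack the epoch arrays once, outside the fold loop
  Yts <- lapply(t_idx, function(t) {
    do.call(cbind, lapply(recordings, function(r) r$data[, , t]))
  })
  fold_scores <- list(); fold_deg <- list()
  for (f in seq_len(cv$n_folds)) {
    train_words <- which(stimuli$block_id %in% fold_blocks(cv, f, FALSE))
    test_words <- which(stimuli$block_id %in% fold_blocks(cv, f, TRUE))
    assert_disjoint(train_words, test_words)
    xsc <- fit_scaler(unclass(embedding)[train_words, , drop = FALSE],
                      "zscore")
    Xs <- apply_scaler(xsc, unclass(embedding))
    sc <- matrix(0, n_sub * n_ch, n_t)
    dg <- matrix(TRUE, n_sub * n_ch, n_t)
    for (ti in seq_along(t_idx)) {
      t <- t_idx[ti]
      Yt <- Yts[[ti]]
      ysc <- fit_scaler(Yt[train_words, , drop = FALSE], "robust")
      # clipping at the train extremes is a no-op on the train rows
      # themselves, so only the held-out rows go through the clip
      Ys_train <- if (ysc$clip_noop) {
        standardize_only(ysc, Yt[train_words, , drop = FALSE])
      } else {
        apply_scaler(ysc, Yt[train_words, , drop = FALSE])
      }
      Ys_test <- apply_scaler(ysc, Yt[test_words, , drop = FALSE])
      fit <- ridge_fit(Xs[train_words, , drop = FALSE], Ys_train, lambdas)
      r <- pearson_score(Ys_test,
                         predict(fit, Xs[test_words, , drop = FALSE]))
      sc[, t] <- as.numeric(r)
      dg[, t] <- attr(r, "degenerate") | ysc$degenerate
    }
    fold_scores[[f]] <- sc
    fold_deg[[f]] <- dg
  }
  avg <- average_fold_scores(fold_scores, fold_deg)
  lapply(seq_len(n_sub), function(s) {
    rows <- (s - 1L) * n_ch + seq_len(n_ch)
    score_map(recordings[[s]]$subject_id, avg$scores[rows, , drop = FALSE],
              attr(embedding, "card"), folds = cv$folds,
              degenerate = avg$degenerate[rows, , drop = FALSE])
  })
}

#' Inter-subject noise ceiling (shared response model)
#'
#' Estimates the explainable signal in one subject's recording by
#' predicting it from the averaged responses of the other subjects to the
#' same sentences: the template response is robust-scaled and mapped to
#' the target through the identical ridge + blocked-CV + Pearson pipeline
#' used for embeddings. Restricted to sentences shared between the target
#' and at least one other subject; per word, the template averages the
#' other subjects who saw that sentence. With a projection operator K,
#' correlations are computed between K-projected observed and predicted
#' responses (e.g. MEG source space).
#'
#' @param recordings List of [brain_recording()] for all subjects (same
#'   grid / epoch axis).
#' @param target_subject Subject id to predict.
#' @param stimuli The [stimulus_set()] (its `subjects` column defines who
#'   saw which sentence).
#' @param cv A [cv_scheme()].
#' @param projection Optional [projection_operator()].
#' @param lambdas Ridge grid.
#' @param delays fMRI scan-attribution delay window (seconds).
#' @param time_indices Optional MEG time restriction.
#' @return A [score_map()] for the target subject; with a projection the
#'   score dimension is sources instead of channels.
#' @export
noise_ceiling <- function(recordings, target_subject, stimuli,
                          cv = NULL, projection = NULL,
                          lambdas = ridge_lambda_grid(),
                          delays = c(2, 4, 6, 8, 10),
                          time_indices = NULL) {
  ids <- vapply(recordings, function(r) r$subject_id, 1L)
  tgt <- recordings[[match(target_subject, ids)]]
  others <- recordings[ids != target_subject]
  if (length(others) < 1) stop("coverage error: need at least 2 subjects",
                               call. = FALSE)
  saw <- function(subjects, id) vapply(subjects, function(s) id %in% s, TRUE)
  tgt_saw <- saw(stimuli$subjects, target_subject)
  other_ids <- setdiff(ids, target_subject)
  n_others_saw <- rowSums(vapply(other_ids,
                                 function(id) saw(stimuli$subjects, id),
                                 logical(nrow(stimuli))))
  shared_words <- which(tgt_saw & n_others_saw > 0)
  if (length(shared_words) == 0) {
    stop("coverage error: no sentences shared between target and others",
         call. = FALSE)
  }
  proj_fun <- if (is.null(projection)) identity else {
    function(m) m %*% t(projection$K)
  }

  if (tgt$modality == "meg") {
    d <- dim(tgt$data)
    template <- array(0, dim = d)
    for (id in other_ids) {
      rec <- others[[match(id, other_ids)]]
      w <- saw(stimuli$subjects, id)
      template[w, , ] <- template[w, , ] + rec$data[w, , ]
    }
    counts <- rowSums(vapply(other_ids, function(id) saw(stimuli$subjects, id),
                             logical(nrow(stimuli))))
    counts[counts == 0] <- 1
    template <- sweep(template, 1, counts, `/`)
    sub <- stimuli[shared_words, , drop = FALSE]
    cv <- cv %||% cv_scheme(sub)
    t_idx <- time_indices %||% seq_len(d[3])
    n_out <- if (is.null(projection)) d[2] else nrow(projection$K)
    fold_scores <- list(); fold_deg <- list()
    for (f in seq_len(cv$n_folds)) {
      train_w <- shared_words[sub$block_id %in% fold_blocks(cv, f, FALSE)]
      test_w <- shared_words[sub$block_id %in% fold_blocks(cv, f, TRUE)]
      assert_disjoint(train_w, test_w)
      sc <- matrix(0, n_out, d[3]); dg <- matrix(TRUE, n_out, d[3])
      for (t in t_idx) {
        Xt <- template[, , t]; Yt <- tgt$data[, , t]
        xsc <- fit_scaler(Xt[train_w, , drop = FALSE], "robust")
        ysc <- fit_scaler(Yt[train_w, , drop = FALSE], "robust")
        Xs <- apply_scaler(xsc, Xt); Ys <- apply_scaler(ysc, Yt)
        fit <- ridge_fit(Xs[train_w, , drop = FALSE],
                         Ys[train_w, , drop = FALSE], lambdas)
        pred <- predict(fit, Xs[test_w, , drop = FALSE])
        r <- pearson_score(proj_fun(Ys[test_w, , drop = FALSE]),
                           proj_fun(pred))
        sc[, t] <- as.numeric(r)
        dg[, t] <- attr(r, "degenerate")
      }
      fold_scores[[f]] <- sc; fold_deg[[f]] <- dg
    }
    avg <- average_fold_scores(fold_scores, fold_deg)
  } else {
    stack <- lapply(others, function(r) r$data)
    template <- Reduce(`+`, stack) / length(stack)
    n_scans <- nrow(tgt$data)
    shared_blocks <- unique(stimuli$block_id[shared_words])
    sstim <- stimuli[stimuli$block_id %in% shared_blocks, , drop = FALSE]
    cv <- cv %||% cv_scheme(sstim)
    scan_sets <- scan_block_sets(stimuli, tgt$tr, delays, n_scans)
    all_blocks <- unique(stimuli$block_id)
    fold_scores <- list(); fold_deg <- list()
    for (f in seq_len(cv$n_folds)) {
      train_blocks <- intersect(fold_blocks(cv, f, FALSE), shared_blocks)
      test_blocks <- intersect(fold_blocks(cv, f, TRUE), shared_blocks)
      train_scans <- scans_for_blocks(scan_sets, train_blocks, all_blocks)
      test_scans <- scans_for_blocks(scan_sets, test_blocks, all_blocks)
      assert_disjoint(train_scans, test_scans)
      xsc <- fit_scaler(template[train_scans, , drop = FALSE], "robust")
      ysc <- fit_scaler(tgt$data[train_scans, , drop = FALSE], "robust")
      Xs <- apply_scaler(xsc, template); Ys <- apply_scaler(ysc, tgt$data)
      fit <- ridge_fit(Xs[train_scans, , drop = FALSE],
                       Ys[train_scans, , drop = FALSE], lambdas)
      pred <- predict(fit, Xs[test_scans, , drop = FALSE])
      r <- pearson_score(proj_fun(Ys[test_scans, , drop = FALSE]),
                         proj_fun(pred))
      fold_scores[[f]] <- as.numeric(r)
      fold_deg[[f]] <- attr(r, "degenerate")
    }
    avg <- average_fold_scores(fold_scores, fold_deg)
  }
  card <- model_card("causal", 1L, 0L, 0L, 0, 0, 0L)  # template provenance
  score_map(target_subject, avg$scores, card, folds = cv$folds,
            degenerate = avg$degenerate)
}
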