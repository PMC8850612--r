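# closed-form ridge solution, the textbook form of the penalized normal
# equations; independent of the SVD path used by ridge_fit
ridge_closed_form <- function(X, Y, lambda) {
  solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, Y))
}

# explicit leave-one-out refit loop (the oracle for the efficient LOO curve)
loo_refit_press <- function(X, Y, lambda) {
  n <- nrow(X)
  press <- matrix(0, 1, ncol(Y))
  for (i in seq_len(n)) {
    W <- ridge_closed_form(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                           lambda)
    press <- press + (Y[i, ] - X[i, , drop = FALSE] %*% W)^2
  }
  as.numeric(press)
}

test_that("scalers fit on train only and flag degenerate columns", {
  X <- cbind(rnorm(50), rep(3, 50))
  sc <- fit_scaler(X, "zscore")
  expect_true(sc$degenerate[2])
  Xs <- apply_scaler(sc, X)
  expect_equal(mean(Xs[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(Xs[, 1]), 1, tolerance = 1e-12)
  expect_true(all(Xs[, 2] == 0))
  # a shifted test split keeps its shift: no leakage of test statistics
  Xtest <- cbind(rnorm(30) + 5, rep(3, 30))
  Xts <- apply_scaler(sc, Xtest)
  expect_gt(abs(mean(Xts[, 1])), 1)
})

test_that("robust scaler clips extreme outliers at train percentiles", {
  set.seed(1)
  x <- rnorm(1e4)
  x[17] <- 1e6
  sc <- fit_scaler(cbind(x), "robust")
  xs <- apply_scaler(sc, cbind(x))
  bound <- (sc$hi - sc$center) / sc$scale
  expect_lte(max(xs), bound + 1e-12)
  expect_lt(max(xs), 10)                      # the outlier is tamed
  # near-standard data pass through essentially unchanged
  z <- rnorm(2000)
  zs <- apply_scaler(fit_scaler(cbind(z), "robust"), cbind(z))
  expect_gt(cor(z, zs), 0.999)
  cs <- fit_scaler(cbind(rep(2, 10)), "robust")
  expect_true(cs$degenerate[1])
  expect_true(all(apply_scaler(cs, cbind(rep(2, 5))) == 0))
})

test_that("ridge_fit matches OLS in the small-lambda limit", {
  set.seed(42)
  X <- matrix(rnorm(200), 50, 4)
  B <- matrix(rnorm(12), 4, 3)
  Y <- X %*% B
  fit <- ridge_fit(X, Y, lambdas = 1e-8)
  expect_equal(fit$W, qr.coef(qr(X), Y), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(ridge_fit(X[1, , drop = FALSE], Y[1, , drop = FALSE]),
               "2 training samples")
  expect_error(ridge_fit(matrix(c(1, NA), 2, 1), matrix(0, 2, 1)), "finite")
})

test_that("efficient LOO curve equals the explicit refit loop", {
  set.seed(7)
  X <- matrix(rnorm(45), 15, 3)
  B <- matrix(rnorm(6), 3, 2)
  Y <- X %*% B + 0.3 * matrix(rnorm(30), 15, 2)
  grid <- ridge_lambda_grid()
  fit <- ridge_fit(X, Y, grid)
  for (j in seq_along(grid)) {
    expect_equal(fit$press[j, ], loo_refit_press(X, Y, grid[j]),
                 tolerance = 1e-8)
  }
  # and the weights solve the penalized normal equations at the selected lambda
  for (k in seq_len(ncol(Y))) {
    expect_equal(fit$W[, k],
                 as.numeric(ridge_closed_form(X, Y[, k, drop = FALSE],
                                              fit$lambda[k])),
                 tolerance = 1e-8)
  }
})

test_that("pure-noise targets select heavier regularization than signal", {
  # calibration of the LOO selection: for the same design, a noise target
  # always wants more shrinkage than a strong noise-free signal target
  grid <- ridge_lambda_grid()
  hits <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(8 * 3), 8, 3)
    l_noise <- ridge_fit(X, matrix(rnorm(8), 8, 1), grid)$lambda[1]
    l_signal <- ridge_fit(X, X %*% c(1, -1, 0.5), grid)$lambda[1]
    if (l_noise > l_signal) hits <- hits + 1L
  }
  expect_gte(hits, 18L)                        # >= 90% of seeds
})

test_that("pearson_score is exact, affine-invariant and symmetric", {
  y <- matrix(c(1, 2, 3, 4), 4, 1)
  yh <- matrix(c(1, 2, 3, 5), 4, 1)
  # hand formula on the printed 4-point pairs
  r_hand <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(as.numeric(pearson_score(y, yh)), r_hand, tolerance = 1e-12)
  expect_equal(as.numeric(pearson_score(y, y)), 1.0)
  expect_equal(as.numeric(pearson_score(y, 2.5 * y + 7)), 1.0,
               tolerance = 1e-12)
  expect_equal(as.numeric(pearson_score(y, yh)),
               as.numeric(pearson_score(yh, y)))
  r0 <- pearson_score(matrix(1, 4, 1), yh)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))
})

test_that("FIR expansion places delayed copies on the scan grid", {
  # single word at t = 0, one unit feature
  Xstar <- fir_expand(matrix(1, 1, 1), onsets = 0, tr = 2,
                      delays = c(2, 4, 6, 8, 10), n_scans = 8)
  expect_equal(dim(Xstar), c(8L, 5L))
  for (k in 1:5) {
    expected <- rep(0, 8)
    expected[1 + k] <- 1                      # delay k*2s = k scans after bin 1
    expect_equal(Xstar[, k], expected)
  }
  expect_true(all(fir_expand(matrix(0, 3, 2), c(0, 1, 4), 2) == 0))
  # two words in the same TR bin are summed
  X2 <- fir_expand(matrix(c(1, 2), 2, 1), onsets = c(0.1, 1.9), tr = 2,
                   delays = 2, n_scans = 4)
  expect_equal(X2[, 1], c(0, 3, 0, 0))
  expect_error(fir_expand(matrix(1, 1, 1), 0, tr = 2, delays = 3),
               "config error")
  expect_warning(fir_expand(matrix(1, 1, 1), 0, tr = 2, delays = 3,
                            nearest_bin = TRUE), "nearest")
})

test_that("blocked CV partitions blocks and rejects starved folds", {
  stim <- grid_stimuli(25)
  cv <- cv_scheme(stim, 5)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), 5L)          # 25 sentences -> 5 blocks
  expect_error(cv_scheme(grid_stimuli(10), 5), "CV error")
  cv_a <- cv_scheme(stim, 5, seed = 3)
  expect_identical(cv_a$folds, cv_scheme(stim, 5, seed = 3)$folds)
})

test_that("fMRI brain scores recover a noise-free forward model", {
  stim <- make_stimuli(n_sentences = 25, seed = 21)
  fam <- make_embedding_family(stim, dim = 6, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 21)
  gen <- fam$embeddings[["step01_layer02"]]
  b <- make_brain(stim, gen, n_subjects = 1, n_channels = 10, snr = Inf,
                  modality = "fmri", kernel = list(type = "onehot", delay = 4),
                  seed = 22)
  sm <- brain_score_fmri(gen, b$recordings[[1]], stim)
  expect_gt(mean(sm$scores[b$truth$responsive]), 0.95)
  # determinism
  sm2 <- brain_score_fmri(gen, b$recordings[[1]], stim)
  expect_identical(sm$scores, sm2$scores)
})

test_that("fMRI brain scores are null for pure-noise recordings", {
  stim <- make_stimuli(n_sentences = 25, seed = 31)
  fam <- make_embedding_family(stim, dim = 6, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 31)
  gen <- fam$embeddings[["step01_layer02"]]
  n_scans <- ceiling((max(stim$onset) + 10) / 2) + 2
  noise <- brain_recording(1L, "fmri",
                           with_seed(77, matrix(rnorm(n_scans * 50),
                                                n_scans, 50)), tr = 2)
  sm <- brain_score_fmri(gen, noise, stim)
  se <- sd(sm$scores) / sqrt(length(sm$scores))
  expect_lt(abs(mean(sm$scores)), 3 * se)
})

test_that("MEG scores peak at the planted latency and are null pre-onset", {
  stim <- make_stimuli(n_sentences = 25, seed = 41)
  fam <- make_embedding_family(stim, dim = 6, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 41)
  gen <- fam$embeddings[["step01_layer02"]]
  times <- seq(-0.5, 2, by = 0.25)
  b <- make_brain(stim, gen, n_subjects = 1, n_channels = 8, snr = 3,
                  modality = "meg", times = times,
                  kernel = list(latency = 0.4, width = 0.05), seed = 42)
  sm <- brain_score_meg(gen, b$recordings[[1]], stim)
  resp <- b$truth$responsive
  prof <- colMeans(sm$scores[resp, , drop = FALSE])
  expect_equal(which.max(prof), which.min(abs(times - 0.4)))
  pre <- which(times < 0)
  pre_scores <- sm$scores[resp, pre]
  se <- sd(pre_scores) / sqrt(length(pre_scores))
  expect_lt(abs(mean(pre_scores)), 3 * se)
  # identical embedding passed twice gives identical maps
  expect_identical(brain_score_meg(gen, b$recordings[[1]], stim)$scores,
                   sm$scores)
})

test_that("per-delay weight norms recover the planted FIR delay", {
  stim <- make_stimuli(n_sentences = 20, seed = 51)
  fam <- make_embedding_family(stim, dim = 5, n_layers = 1, n_steps = 1,
                               signal_mix_curve = 1, seed = 51)
  gen <- fam$embeddings[["step01_layer01"]]
  delays <- c(2, 4, 6, 8, 10)
  for (d in c(2, 6, 10)) {
    b <- make_brain(stim, gen, n_subjects = 1, n_channels = 6, snr = 10,
                    modality = "fmri", kernel = list(type = "onehot", delay = d),
                    seed = 50 + d)
    rec <- b$recordings[[1]]
    xsc <- fit_scaler(unclass(gen), "zscore")
    Xstar <- fir_expand(apply_scaler(xsc, unclass(gen)), stim$onset, rec$tr,
                        delays, nrow(rec$data))
    ysc <- fit_scaler(rec$data, "robust")
    fit <- ridge_fit(Xstar, apply_scaler(ysc, rec$data))
    o <- ncol(gen)
    norms <- vapply(seq_along(delays), function(k) {
      sqrt(sum(fit$W[(k - 1) * o + seq_len(o), b$truth$responsive]^2))
    }, 1)
    expect_equal(delays[which.max(norms)], d)
  }
})

test_that("noise ceiling is exact for identical noise-free subjects", {
  stim <- make_stimuli(n_sentences = 25, n_subjects = 3,
                       sentences_per_subject = 25, seed = 61)
  fam <- make_embedding_family(stim, dim = 6, n_layers = 2, n_steps = 1,
                               signal_mix_curve = 1, seed = 61)
  gen <- fam$embeddings[["step01_layer02"]]
  times <- seq(-0.5, 2, by = 0.5)
  b <- make_brain(stim, gen, n_subjects = 3, n_channels = 8, snr = Inf,
                  modality = "meg", times = times, seed = 62)
  peak <- which.max(b$truth$kernel_curve)
  nc <- noise_ceiling(b$recordings, 1, stim, time_indices = peak)
  resp <- b$truth$responsive
  expect_equal(unname(nc$scores[resp, peak]), rep(1, sum(resp)),
               tolerance = 1e-6)
  # identity projection changes nothing
  K <- projection_operator(diag(8))
  ncp <- noise_ceiling(b$recordings, 1, stim, projection = K,
                       time_indices = peak)
  expect_equal(ncp$scores, nc$scores, tolerance = 1e-12)
})

test_that("noise ceiling requires shared sentences", {
  stim <- make_stimuli(n_sentences = 25, n_subjects = 2,
                       sentences_per_subject = 25, seed = 71)
  df <- as.data.frame(stim)
  df$subjects <- lapply(df$sentence_id, function(s) {
    if (s < 13) 1L else 2L                      # disjoint assignment
  })
  stim2 <- stimulus_set(df)
  fam <- make_embedding_family(stim2, dim = 4, n_layers = 1, n_steps = 1,
                               signal_mix_curve = 1, seed = 71)
  b <- make_brain(stim2, fam$embeddings[[1]], n_subjects = 2, n_channels = 6,
                  snr = 2, modality = "meg", times = seq(-0.5, 2, by = 0.5),
                  seed = 72)
  expect_error(noise_ceiling(b$recordings, 1, stim2, time_indices = 2L),
               "coverage error")
})

test_that("batched multi-subject scoring equals per-subject scoring", {
  stim <- make_stimuli(n_sentences = 25, seed = 81)
  fam <- make_embedding_family(stim, dim = 5, n_layers = 1, n_steps = 1,
                               signal_mix_curve = 1, seed = 81)
  emb <- fam$embeddings[["step01_layer01"]]
  b <- make_brain(stim, emb, n_subjects = 3, n_channels = 6, snr = 1,
                  modality = "meg", times = seq(-0.5, 2, by = 0.5), seed = 82)
  cv <- cv_scheme(stim)
  grp <- brain_score_meg_group(emb, b$recordings, stim, cv = cv)
  for (s in 1:3) {
    solo <- brain_score_meg(emb, b$recordings[[s]], stim, cv = cv)
    expect_equal(grp[[s]]$scores, solo$scores, tolerance = 1e-12)
    expect_identical(grp[[s]]$degenerate, solo$degenerate)
  }
})
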