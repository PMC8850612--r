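make_map <- function(subject, scores, card = random_card(),
                     degenerate = NULL) {
  score_map(subject, scores, card, degenerate = degenerate)
}

test_that("gain is zero on identity, antisymmetric and additive", {
  a <- make_map(1L, matrix(runif(12, -0.5, 0.5), 3, 4))
  b <- make_map(1L, matrix(runif(12, -0.5, 0.5), 3, 4))
  c3 <- make_map(1L, matrix(runif(12, -0.5, 0.5), 3, 4))
  expect_true(all(gain(a, a)$delta == 0))
  expect_identical(gain(a, b)$delta, -gain(b, a)$delta)
  expect_identical(gain(a, c3)$delta, gain(a, b)$delta + gain(b, c3)$delta)
  expect_error(gain(a, make_map(2L, matrix(0, 3, 4))), "same subject")
  expect_error(gain(a, make_map(1L, matrix(0, 2, 4))), "target grid")
})

test_that("average_scores honors masks, time restriction and flags", {
  m <- make_map(1L, matrix(0.25, 4, 6))
  expect_equal(average_scores(m), 0.25)
  # mask of k channels: arithmetic mean over exactly those rows
  scores <- matrix(seq(0.01, 0.24, length.out = 24), 4, 6)
  m2 <- make_map(1L, scores)
  mask <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(average_scores(m2, mask = mask),
               mean(scores[c(1, 3), ]))
  expect_equal(average_scores(m2, time_indices = c(2, 5)),
               mean(scores[, c(2, 5)]))
  deg <- matrix(FALSE, 4, 6); deg[1, ] <- TRUE
  m3 <- make_map(1L, scores, degenerate = deg)
  expect_equal(average_scores(m3), mean(scores[-1, ]))
  expect_error(average_scores(m2, mask = rep(FALSE, 4)), "empty mask")
})

test_that("convergence equals the textbook Pearson formula per subject", {
  maps <- list()
  acc <- seq(0.1, 0.4, length.out = 6)
  set.seed(5)
  truth <- list()
  for (s in 1:3) {
    sc <- 0.1 * acc + rnorm(6, sd = 0.005)
    truth[[s]] <- sc
    for (k in 1:6) {
      card <- random_card(acc = acc[k], step = k * 100)
      maps[[length(maps) + 1L]] <- make_map(s, matrix(sc[k], 2, 2), card)
    }
  }
  tab <- comparison_table(maps)
  conv <- convergence(tab, "accuracy_top1")
  for (s in 1:3) {
    x <- acc; y <- truth[[s]]
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(conv$r[conv$subject == s], r_hand, tolerance = 1e-12)
  }
  # training_step key works and constant scores degrade gracefully
  conv2 <- convergence(tab, "training_step")
  expect_false(any(conv2$degenerate))
  flat <- lapply(1:6, function(k) {
    make_map(9L, matrix(0.2, 2, 2), random_card(acc = acc[k]))
  })
  cflat <- convergence(comparison_table(flat), "accuracy_top1")
  expect_true(cflat$degenerate[1])
  expect_equal(cflat$r[1], 0)                  # flagged, not NaN
})

test_that("shuffled accuracy breaks the convergence correlation", {
  set.seed(11)
  acc <- seq(0.05, 0.45, length.out = 10)
  rs <- replicate(50, {
    sc <- 0.2 * sample(acc) + rnorm(10, sd = 0.01)   # scores tied to SHUFFLED acc
    cor(sc, acc)
  })
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se)
})

test_that("layer profile finds the best depth and the middle band", {
  # monotone family: scores increase with depth -> argmax at last layer
  maps <- list()
  for (l in 0:4) {
    maps[[l + 1]] <- make_map(1L, matrix(0.05 * l, 2, 2),
                              random_card(layer_index = l, n_layers = 4L))
  }
  prof <- layer_profile(comparison_table(maps))
  expect_equal(prof$best_layer, 4L)
  expect_false(prof$in_middle)
  # hump at mid depth -> argmax inside [n/2, 3n/4]
  hump <- c(0.0, 0.1, 0.3, 0.25, 0.05)
  maps2 <- lapply(0:4, function(l) {
    make_map(1L, matrix(hump[l + 1], 2, 2),
             random_card(layer_index = l, n_layers = 4L))
  })
  prof2 <- layer_profile(comparison_table(maps2))
  expect_equal(prof2$best_layer, 2L)
  expect_true(prof2$in_middle)
  # single layer: trivial profile
  prof1 <- layer_profile(comparison_table(list(
    make_map(1L, matrix(0.2, 2, 2), random_card(layer_index = 1L,
                                                n_layers = 1L)))))
  expect_equal(nrow(prof1$profile), 1L)
})

test_that("residualizing an embedding against itself leaves pure noise", {
  stim <- grid_stimuli(5)
  set.seed(3)
  m2 <- embedding_matrix(matrix(rnorm(nrow(stim) * 4), ncol = 4),
                         stim$word_id, random_card())
  m1 <- embedding_matrix(unclass(m2) %*% matrix(rnorm(16), 4, 4),
                         stim$word_id, random_card())
  res <- residualize_embedding(m1, m2)
  expect_lt(max(abs(unclass(res))), 1e-8)      # m1 lies in m2's span
})
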