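importance_features <- c("task", "n_heads", "n_layers", "dim",
                         "training_step", "accuracy_top1", "layer_position")

#' Property table for the feature-importance analysis
#'
#' One row per embedding and subject: the seven model properties used as
#' predictors (training task, attention heads, layers, dimensionality,
#' training step, top-1 accuracy, relative layer position) and the
#' subject's average brain score as the target.
#'
#' @param table A [comparison_table()] (already holds the card fields and
#'   averaged scores).
#' @return A tibble with the feature columns, `subject` and `score`; the
#'   categorical task is encoded as a binary indicator
#'   (`task = 1` for causal, 0 for masked).
#' @export
property_table <- function(table) {
  if (any(!table$task %in% c("causal", "masked"))) {
    stop("property_table covers language models only (causal/masked)",
         call. = FALSE)
  }
  if (any(is.na(table$score))) {
    stop("property_table: missing target scores", call. = FALSE)
  }
  tibble::tibble(
    subject = table$subject,
    task = as.numeric(table$task == "causal"),
    n_heads = as.numeric(table$n_heads),
    n_layers = as.numeric(table$n_layers),
    dim = as.numeric(table$dim),
    training_step = as.numeric(table$training_step),
    accuracy_top1 = as.numeric(table$accuracy_top1),
    layer_position = as.numeric(table$layer_position),
    score = table$score)
}

#' Random-forest permutation feature importance of brain scores
#'
#' For each subject separately, a random-forest regressor predicts the
#' average brain score of every embedding from the seven model properties,
#' evaluated with a Pearson correlation R under five-fold cross-validation
#' across embeddings. The importance of a feature is the decrease in
#' held-out R when that feature's column is shuffled within the held-out
#' fold (50 repetitions), averaged across folds — its unique contribution
#' to explaining score variability.
#'
#' @param table A [property_table()].
#' @param n_trees Number of trees (default 500; no tuning is performed).
#' @param n_repeats Shuffles per feature and fold (default 50).
#' @param n_folds Cross-validation folds across embeddings (default 5).
#' @param seed Integer seed (forest and shuffles are deterministic per
#'   subject given the seed).
#' @return A list: `$importance` (tibble `subject`, `feature`, `delta_r`)
#'   and `$fit` (tibble `subject`, `r`, `degenerate`). Subjects with a
#'   constant target are flagged degenerate with `delta_r = 0`.
#' @export
fit_importance <- function(table, n_trees = 500L, n_repeats = 50L,
                           n_folds = 5L, seed = 1L) {
  subjects <- unique(table$subject)
  imp_rows <- list(); fit_rows <- list()
  for (s in subjects) {
    sub <- as.data.frame(table[table$subject == s,
                               c(importance_features, "score")])
    n <- nrow(sub)
    if (n < 2 * n_folds) {
      stop("fit_importance needs at least 2 rows per fold", call. = FALSE)
    }
    if (sd(sub$score) == 0) {
      imp_rows[[length(imp_rows) + 1L]] <- tibble::tibble(
        subject = s, feature = importance_features, delta_r = 0)
      fit_rows[[length(fit_rows) + 1L]] <- tibble::tibble(
        subject = s, r = 0, degenerate = TRUE)
      next
    }
    folds <- with_seed(seed + 7L * s,
                       sample(rep(seq_len(n_folds), length.out = n)))
    r_fold <- numeric(n_folds)
    drop_fold <- matrix(0, n_folds, length(importance_features),
                        dimnames = list(NULL, importance_features))
    for (f in seq_len(n_folds)) {
      train <- sub[folds != f, , drop = FALSE]
      test <- sub[folds == f, , drop = FALSE]
      forest <- with_seed(seed + 131L * s + f,
        ranger::ranger(score ~ ., data = train, num.trees = n_trees,
                       num.threads = 1L,
                       seed = (seed + 131L * s + f) %% .Machine$integer.max))
      pred <- predict(forest, test, num.threads = 1L)$predictions
      r_fold[f] <- safe_cor(test$score, pred)
      perm_idx <- with_seed(seed + 977L * s + f, {
        lapply(seq_len(n_repeats), function(k) sample(nrow(test)))
      })
      for (feat in importance_features) {
        # one stacked prediction call over all shuffle repetitions
        stacked <- test[rep(seq_len(nrow(test)), n_repeats), , drop = FALSE]
        shuffled_col <- unlist(lapply(perm_idx, function(ix) test[[feat]][ix]))
        stacked[[feat]] <- shuffled_col
        pp <- predict(forest, stacked, num.threads = 1L)$predictions
        pp <- matrix(pp, nrow(test), n_repeats)
        r_perm <- vapply(seq_len(n_repeats),
                         function(k) safe_cor(test$score, pp[, k]), 1)
        drop_fold[f, feat] <- r_fold[f] - mean(r_perm)
      }
    }
    imp_rows[[length(imp_rows) + 1L]] <- tibble::tibble(
      subject = s, feature = importance_features,
      delta_r = colMeans(drop_fold))
    fit_rows[[length(fit_rows) + 1L]] <- tibble::tibble(
      subject = s, r = mean(r_fold), degenerate = FALSE)
  }
  list(importance = do.call(rbind, imp_rows), fit = do.call(rbind, fit_rows))
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Rank features by importance and compare adjacent pairs across subjects
#'
#' Orders the features by mean permutation importance (across subjects)
#' and tests each ordered adjacent pair with a Wilcoxon signed-rank test
#' on the per-subject importance differences — the "ordered pairwise
#' comparisons" summary of a feature-importance figure.
#'
#' @param importance The `$importance` tibble from [fit_importance()].
#' @return A list: `$ranking` (tibble `feature`, `mean_delta_r`, ordered
#'   decreasing) and `$pairs` (tibble `feature_high`, `feature_low`, `p`);
#'   `$pairs` is empty with a single feature.
#' @export
rank_and_compare <- function(importance) {
  feats <- unique(importance$feature)
  means <- vapply(feats, function(f) {
    mean(importance$delta_r[importance$feature == f])
  }, 1)
  ord <- order(means, decreasing = TRUE)
  ranking <- tibble::tibble(feature = feats[ord], mean_delta_r = means[ord])
  if (length(feats) < 2) {
    return(list(ranking = ranking,
                pairs = tibble::tibble(feature_high = character(0),
                                       feature_low = character(0),
                                       p = numeric(0))))
  }
  subjects <- unique(importance$subject)
  by_feat <- lapply(feats[ord], function(f) {
    sub <- importance[importance$feature == f, ]
    sub$delta_r[match(subjects, sub$subject)]
  })
  pairs <- do.call(rbind, lapply(seq_len(length(feats) - 1L), function(i) {
    tibble::tibble(feature_high = ranking$feature[i],
                   feature_low = ranking$feature[i + 1L],
                   p = wilcoxon_vs_zero(by_feat[[i]] - by_feat[[i + 1L]]))
  }))
  list(ranking = ranking, pairs = pairs)
}
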