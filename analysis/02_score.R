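#!/usr/bin/env Rscript
# Stage 2 — brain scores: for every subject and every embedding of the
# family, fit the ridge encoding model (per-channel leave-one-out lambda
# selection, blocked 5-fold CV) at each retained epoch time sample, and
# average the held-out Pearson correlations. Also scores the three
# representation levels (visual / lexical / compositional).
source("analysis/00_config.R")

res <- run_pipeline(study_config, study_dir, stages = "score")

cat("per-level average brain scores (across channels, times, subjects):\n")
lvl <- res$level_table
for (l in c("visual", "lexical", "compositional")) {
  cat(sprintf("  %-14s R = %.4f\n", l, mean(lvl$score[lvl$level == l])))
}
cat("wrote", file.path(study_dir, "scores.tsv"), "and level score maps\n")
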