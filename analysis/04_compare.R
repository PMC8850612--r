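#!/usr/bin/env Rscript
# Stage 4 — model comparison: gains between representation levels
# (word over visual, compositional over word), the layer profile across
# depth, and the convergence correlation between brain score and planted
# word-prediction accuracy across checkpoints (middle layers).
source("analysis/00_config.R")

res <- run_pipeline(study_config, study_dir, stages = "compare")

cat("per-subject gains (delta R):\n")
print(res$gain_table)
cat("\nlayer profile (mean score per depth):\n")
print(res$layers$profile)
cat(sprintf("best layer: %d (in middle band: %s)\n",
            res$layers$best_layer, res$layers$in_middle))
cat("\nconvergence (brain score vs planted accuracy, per subject):\n")
print(res$convergence)
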