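#!/usr/bin/env Rscript
# Stage 1 — simulate the study: a word-by-word stimulus stream (sentences
# of 9-15 words in 5-sentence blocks), a family of embeddings with a
# planted accuracy curve, and multi-subject MEG-like recordings generated
# from the deepest final-checkpoint embedding through a shared linear
# forward model. Also runs the toy extraction providers over the causal
# 3-sentence context windows.
source("analysis/00_config.R")

res <- run_pipeline(study_config, study_dir,
                    stages = c("simulate", "extract"))

stim <- res$stimuli
cat(sprintf("stimuli: %d words, %d sentences, %d blocks\n",
            nrow(stim), length(unique(stim$sentence_id)),
            length(unique(stim$block_id))))
cat(sprintf("mean word duration: %.0f ms (target 351 ms)\n",
            1000 * mean(stim$duration)))
cat(sprintf("embedding family: %d embeddings (%d checkpoints x %d layers)\n",
            length(res$family$embeddings), study_config$family$n_steps,
            study_config$family$n_layers + 1L))
cat(sprintf("recordings: %d subjects x %d channels, SNR %.1f\n",
            length(res$recordings), study_config$brain$n_channels,
            study_config$brain$snr))
cat("arrays written under", file.path(study_dir, "arrays"), "\n")
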