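#!/usr/bin/env Rscript
# Stage 3 — inter-subject noise ceiling (shared response model): predict
# each subject's responses from the averaged responses of the others to
# the same sentences, through the identical ridge + blocked-CV pipeline.
# The ceiling bounds how much of the signal any encoding model could
# explain.
source("analysis/00_config.R")

res <- run_pipeline(study_config, study_dir, stages = "ceiling")

print(res$ceiling_table)
cat(sprintf("mean noise ceiling R = %.4f\n",
            mean(res$ceiling_table$ceiling)))
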