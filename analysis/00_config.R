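# Shared study configuration for the numbered analysis scripts.
# Everything downstream is a pure function of (config, seed); rerunning any
# script reproduces its outputs bit-identically.
library(brainscore)

study_seed <- 1L
study_dir <- "results/run"
study_config <- default_config(study_seed)
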