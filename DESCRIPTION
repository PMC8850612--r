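Package: brainscore
Title: Ridge Encoding Models and Brain Scores for Language Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the similarity between artificial neural
    network activations and neuroimaging recordings with cross-validated
    ridge encoding models ("brain scores"). Implements per-target ridge
    regression with efficient leave-one-out regularization selection, finite
    impulse response expansion for hemodynamically delayed BOLD responses,
    blocked cross-validation without train/test leakage, an inter-subject
    noise ceiling (shared response model), gain decomposition between
    representation levels (visual, lexical, compositional), convergence
    analysis across training checkpoints, random-forest permutation feature
    importance over model properties, and group-level statistics (Wilcoxon
    signed-rank with Benjamini-Hochberg false discovery rate control). A
    synthetic-data module generates word-by-word stimulus streams, embedding
    families with planted ground truth, and multi-subject fMRI/MEG-like
    responses so the full pipeline is testable without access to restricted
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ggplot2
Config/testthat/edition: 3
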