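---
title: "Encoding models, brain scores and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding models, brain scores and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(brainscore)
```

This vignette is the package's account of its methods: the encoding model
and its assumptions, the parameters that matter, what the synthetic data
generator does and does not emulate, and the numerical and design choices
made where the procedure was genuinely open.

## The encoding model

The core quantity is the **brain score**: the cross-validated Pearson
correlation between recorded brain responses and the predictions of a
ridge regression from stimulus features. For one subject, features
$X \in \mathbb{R}^{w \times o}$ (one activation vector per word) and
responses $Y \in \mathbb{R}^{w \times n}$ (per voxel or per MEG channel),
the fitted map is

$$W = (X_\mathrm{train}^\top X_\mathrm{train} + \lambda I)^{-1}
      X_\mathrm{train}^\top Y_\mathrm{train},$$

evaluated as $R = \mathrm{Corr}(Y_\mathrm{test}, \hat Y_\mathrm{test})$
per target dimension. The model is deliberately linear: a high score
means the information is *linearly readable* from the features, not
merely present in some entangled form.

Assumptions worth keeping in mind: responses are treated as stationary
within a session; the mapping is fitted independently per subject; and
for fMRI the hemodynamic response is modelled non-parametrically by a
finite impulse response (FIR) basis rather than a fixed canonical shape.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `lambdas` | 20 values, log-spaced $10^{-3}$–$10^{8}$ | — | wide enough to span near-OLS to near-total shrinkage |
| λ selection | exact LOO per target | — | each voxel/channel has its own noise level |
| CV folds | 5, grouped by 5-sentence blocks | — | sentences within a block are temporally adjacent; grouping prevents leakage |
| FIR delays | 2, 4, 6, 8, 10 | s | covers the BOLD lag at TR = 2 s |
| X scaling | z-score on training words | — | puts feature dimensions on one scale for a single λ grid |
| Y scaling | clip at train 0.01st/99.99th percentiles, then standardize | — | tames rare artifacts without distorting the bulk |
| MEG epoch | −0.5 … +2.0 | s | covers pre-onset baseline and late responses |
| MEG subsampling | 10 samples in [0, 2] | s | cheap axis for model-comparison averages |

The λ selection uses the algebraic identity between leave-one-out
residuals and ridge leverages: with $X = U D V^\top$,
$e_i = (y_i - \hat y_i)/(1 - h_{ii})$ where
$h_{ii} = \sum_k u_{ik}^2 d_k^2/(d_k^2 + \lambda)$. The test suite
asserts equality with an explicit refit loop at every grid point to
$10^{-8}$; ties in the LOO error resolve to the smallest λ. Internally
the PRESS column sums are expanded into quadratic forms so the per-λ
cost is one BLAS product; a batched scorer
(`brain_score_meg_group()`) stacks the channels of many subjects into
one response matrix — every step of the pipeline is columnwise
independent, so this is exactly equivalent to per-subject calls (also
asserted in the tests) and much faster.

## Leakage control

Fold assignment lives at the block level, and the scoring functions
assert train/test disjointness as a hard failure, not a warning. For
fMRI, block boundaries blur on the scan grid because of the hemodynamic
lag: a scan is attributed to the blocks that reach it through any FIR
delay, and scans receiving contributions from both train and test
blocks are dropped. This is stricter than rounding the boundary either
way and costs a few scans per fold seam.

Scalers are fitted on the training split only and applied unchanged to
the test split. The clip bounds of the robust scaler are inverse-ECDF
(type-1) quantiles, i.e. observed values: with fewer than $10^4$
training samples the 0.01st/99.99th percentiles are the column extremes,
so clipping the training data is a no-op while genuinely extreme
held-out values are still clamped to the training range.

## Degenerate targets

Zero-variance columns (a flat voxel, a pre-onset MEG sample in
noise-free synthetic data) are never dropped: they score 0 and carry a
degenerate flag, so score maps keep a fixed shape and downstream
averages can honour the flag (`average_scores()` excludes flagged
entries). Correlations are clamped to $[-1, 1]$ against floating-point
spill.

## The noise ceiling

The inter-subject noise ceiling reuses the identical pipeline with the
design matrix replaced by the average response of the other subjects to
the same sentences, restricted to sentences the target shares with at
least one other subject; per word the template averages exactly the
subjects who saw that sentence. For MEG this happens per time sample at
the word level. For fMRI both template and target live on the scan
grid, and the scan-to-block attribution reuses the FIR delay window so
hemodynamically delayed scans follow their block through
cross-validation. An optional projection operator K (e.g. a
sensor-to-source inverse operator) is applied to both observed and
predicted responses before the correlation.

## The synthetic generator

The generator's defaults mirror the reading-protocol structure the
package targets: sentences of 9–15 words, word durations drawn from a
shifted gamma with mean 351 ms and floor 300 ms (the protocol reports
only mean and range, so a right-skewed two-parameter family is the
minimal choice), 300 ms blanks between words, 5 s between sentences,
and blocks of five consecutive sentences.

Embeddings are planted at three nested levels: *visual-like* word-form
features (length and hashed character bigrams), a *lexical-like*
word-identity lookup, and a *compositional-like* signal — the causal,
exponentially decaying average of the lexical vectors over the sentence
so far — mixed in increasingly with layer depth (layer 0 is the pure
token-level lookup, the deepest layer pure compositional). A checkpoint
at mix level $\alpha_t$ is $(1-\alpha_t)\,\mathrm{noise} +
\alpha_t\,\mathrm{signal}$, and its planted top-1 accuracy is
$0.46\,\alpha_t$ — 46% being the ceiling reached by well-trained causal
models — so convergence analyses have a known monotone target. The
accuracy is a planted label, not a measured prediction accuracy;
convergence tests are against this label.

Brain responses come from a shared linear forward model $G$
(dimensions × channels) whose columns are zeroed outside a responsive
subset. fMRI uses a one-hot FIR kernel at a configurable delay — chosen
over a double-gamma shape so delay-recovery tests have an exact ground
truth (a smooth gamma option exists for realism). MEG multiplies the
projected features by a causal Gaussian latency kernel (zero before
word onset). The realized noise is standardized per channel (and per
time sample in MEG) before scaling, so the achieved signal-to-noise
variance ratio equals the request exactly; a configurable fraction of
noise variance is shared across subjects, which is what gives the noise
ceiling something to find. Noise is white by default with an AR(1)
option — the temporal noise spectrum of real recordings is not
otherwise emulated, and neither are sensor physics, spatial
autocorrelation, or subject-specific hemodynamics. Passing tests on
this generator therefore demonstrates the correctness of the machinery
and the recoverability of planted structure, not performance on real
data.

## Design choices on open points

- **Robust scaler**: "clip then standardize" is implemented as clip at
  the percentile bounds, then mean/std standardization (configurable);
  median/IQR would also be defensible, but mean/std keeps the scaler
  consistent with the z-scoring of X.
- **fMRI responses live on the scan grid**, the only construction
  consistent with an FIR expansion of word features into TR bins.
- **Causal context windows** (three preceding sentences plus the
  sentence so far) do not cross run boundaries but do cross block
  boundaries: blocks are a cross-validation artifact, runs are genuine
  recording breaks.
- **Middle layers** are the integer indices in $[n/2, 3n/4]$, both ends
  inclusive — for a 12-layer stack, layers 6–9.
- **Layer convention**: `n_layers` counts contextual layers; the
  word-embedding layer is index 0 and `layer_position` is
  `layer_index / n_layers`.
- **Wilcoxon zeros** are dropped (the original signed-rank rule); the
  exact distribution is used for $n \le 25$ without ties.
- **FDR pooling**: for MEG the correction pools channels and time
  samples jointly — one analysis, one family of tests.
- **Gain comparisons** are raw score differences; a residualization
  mode (`residualize_embedding()`) regresses one embedding out of
  another for orthogonalized comparisons but is not the default.
- **Random forest**: 500 trees, no tuning; the permutation importance
  shuffles a feature within the held-out fold, 50 repetitions, averaged
  over 5 folds. Tree count is a stability choice, documented as such.

## Problem sizes

The shipped study (`default_config()`) uses 25 sentences, 6 subjects,
16 channels, a 5-checkpoint × 4-layer family, and 10 retained time
samples — a deliberate desk-scale choice that runs in well under a
minute while exercising every stage. The property tests run larger
designs where the property demands it (e.g. 20 subjects × 200 locations
× 200 replicates for the FDR calibration of the group map, and 40-seed
recovery loops for FIR delays and feature importance). At 6 subjects
the per-location group map cannot survive FDR correction (the minimum
two-sided Wilcoxon p is $2/2^6$); the spatially averaged gain is the
group quantity the demo reports, and per-location inference is expected
to engage only at realistic cohort sizes.

## Known limitations

- No ingest adapters for NIfTI/FIF: preprocessing of real recordings is
  out of scope, and arrays enter through the package's plain-text
  containers.
- The toy activation providers are deterministic stand-ins honouring
  the extraction contract (causality, layer-0 context independence);
  they are not trained networks, and nothing about their representational
  content should be over-interpreted.
- The noise ceiling assumes subjects share a common response up to
  noise; systematic inter-subject differences (anatomy, latency shifts)
  are not modelled by the generator and would lower real ceilings.
- Permutation importance inherits the usual caveat for correlated
  features: shared information is split, so importances are not
  additive and only the planted-dominance ordering is asserted.
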