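# brainscore

Cross-validated ridge encoding models ("brain scores") for comparing the
activations of language models with fMRI and MEG responses to sentences —
plus everything around them: an inter-subject noise ceiling, gain
decomposition between representation levels, convergence analysis across
training checkpoints, random-forest permutation feature importance over
model properties, and group-level statistics. A synthetic-data module
generates stimulus streams, embedding families and multi-subject brain
responses with planted ground truth, so the entire pipeline is testable
and demonstrable without access to restricted neuroimaging data.

## Who this is for

Researchers in computational neuroscience who fit voxel-/sensor-wise
encoding models from stimulus features (e.g. transformer activations) to
brain recordings, and who need the statistical scaffolding around that
fit — leakage-free blocked cross-validation, per-target regularization,
hemodynamic lag modelling, noise ceilings, and second-level inference —
as tested, reusable functions rather than one-off scripts.

## The model

For each subject, a linear map **W** predicts the brain response **Y**
(voxels on the scanner grid, or MEG channels at each epoch time sample)
from stimulus features **X** (one activation vector per word):

    W = (XᵀX + λI)⁻¹ XᵀY

λ is chosen per target dimension from 20 values log-spaced in
[10⁻³, 10⁸] by exact leave-one-out cross-validation on the training
split (computed in closed form from one SVD, and verified in the tests
against an explicit refit loop). The map is evaluated by the Pearson
correlation R between predicted and held-out responses — the **brain
score** — under 5-fold cross-validation grouped by 5-sentence blocks, so
no block ever spans train and test. For fMRI, **X** is expanded with a
finite impulse response model (5 delays, 2–10 s) to capture the
hemodynamic lag; for MEG the model is fitted at each time sample
independently. **X** is z-scored across training words; **Y** passes
through a robust scaler clipping at the training 0.01st/99.99th
percentiles before standardization.

Derived analyses:

- **Noise ceiling** — the same pipeline with **X** replaced by the
  average response of all other subjects to the same sentences (an
  estimate of explainable signal; optionally correlated after a linear
  source projection K).
- **Gain** ΔR = R(M₁) − R(M₂) — the score difference between two
  embeddings on the same targets, attributing signal to representation
  levels (visual → lexical → compositional).
- **Convergence** — per subject, the correlation between a checkpoint's
  average brain score and its word-prediction accuracy (or training
  step); positive values mean better language models map better onto
  the brain.
- **Permutation feature importance** — a random forest predicts average
  brain scores from seven model properties (task, heads, layers,
  dimensionality, training step, accuracy, layer position); a feature's
  importance is the drop in held-out R when it is shuffled (50 repeats,
  5-fold CV).
- **Group statistics** — Wilcoxon signed-rank across subjects per
  location, Benjamini–Hochberg FDR jointly across locations, SEM error
  bars.

## Worked example

The numbered scripts under `analysis/` run a complete synthetic study
(6 subjects, 25 sentences in 5-word-sentence blocks, a 5-checkpoint ×
4-layer embedding family driving 16 MEG-like channels at SNR 2):

```sh
Rscript analysis/01_simulate.R   # stimuli, embeddings, recordings
Rscript analysis/02_score.R      # brain scores for every embedding
Rscript analysis/03_ceiling.R    # inter-subject noise ceiling
Rscript analysis/04_compare.R    # gains, layer profile, convergence
Rscript analysis/05_importance.R # permutation feature importance
Rscript analysis/06_report.R     # group statistics + manifest
```

Output of `02_score.R`–`04_compare.R` (seed 1):

```
per-level average brain scores (across channels, times, subjects):
  visual         R = 0.0204
  lexical        R = 0.0722
  compositional  R = 0.0797
mean noise ceiling R = 0.5450
best layer: 2 (in middle band: TRUE)
convergence r (per subject): 0.94 – 0.98
```

The hierarchy visual < lexical < compositional mirrors how the generator
plants signal (recordings are driven by the compositional embedding);
the compositional-over-word gain is positive in every subject and
significant across the group (Wilcoxon p = 0.031); the best-scoring
layer falls in the middle band [n/2, 3n/4] of the stack; and the
convergence correlation recovers the planted link between accuracy and
brain score. All artifacts land under `results/run/` with a
`manifest.json` of checksums — rerunning with the same seed reproduces
them bit-identically.

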