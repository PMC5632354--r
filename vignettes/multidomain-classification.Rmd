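---
title: "Multi-domain classification of ADHD: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain classification of ADHD: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhdml)
```

## The problem and the approach

ADHD diagnosis rests on clinical interview, observation and rating scales —
subjective instruments whose reliability suffers under the disorder's
heterogeneity. `adhdml` implements a supervised machine-learning pipeline
that asks how well three objective measurement domains, alone and combined,
separate school-aged children with ADHD from typically developing (TD)
peers:

* **NPS** — 18 neuropsychological scores from computerized tests of
  vigilance, focused and sustained attention, and cognitive flexibility;
* **BIO** — 10 blood fatty-acid markers (individual omega-3/omega-6
  percentages, ratios, and pooled saturated/monounsaturated/polyunsaturated
  totals);
* **NIRS** — task-evoked cortical hemoglobin responses (oxygenated and
  deoxygenated, treated as separate domains `NIRS_OXY` / `NIRS_DEOXY`)
  measured by functional near-infrared spectroscopy over bilateral
  frontotemporal cortex while the child performs a visuospatial N-back
  working-memory task.

Each domain trains its own linear support vector machine inside a nested
cross-validation with exhaustive wrapper feature selection; the
domain-specific predictive models are then combined by majority vote.

## The stimulation protocol and fNIRS preprocessing

The N-back protocol is fixed: thirteen segments in the order
rest–C–1B–2B–rest–1B–C–2B–rest–2B–1B–C–rest, where C is a control task
(respond to the centre location), 1B and 2B are 1-back and 2-back
working-memory loads. The first rest lasts 60 s, later rests 30 s; every
task block opens with an instruction screen (2 s for C, 3 s for 1B/2B)
followed by 32 stimuli of 0.5 s at a 1.5 s inter-stimulus interval — a 64 s
stimulation period, 750 s in total. `make_schedule()` returns this schedule
and is the single source of timing truth for both the generator and the
preprocessing.

Preprocessing per subject and chromophore (`nirs_feature_table()`):

1. **Low-pass filtering** at 0.3 Hz keeps the task/rest frequency and
   removes cardiac/respiratory components. The filter is a 4th-order
   Butterworth applied forward–backward (`signal::filtfilt`), i.e.
   zero-phase, so the block response is not delayed; only the cutoff is a
   protocol constant, the order and zero-phase application are this
   package's choices.
2. **Epoching**: one epoch per task block, from 14 s before to 14 s after
   the stimulation period. We anchor the epoch at the *first stimulus*
   (after the instruction screen), which makes every epoch exactly
   14 + 64 + 14 = 92 s; the instruction falls in the pre-window. Nine
   epochs result, three per condition.
3. **Baseline z-scoring**: raw fNIRS amplitudes are relative and not
   comparable across subjects or channels, so each epoch/channel is
   standardized by the mean and SD of its own 3 s baseline immediately
   before the first stimulus: `z = (x_task − m_baseline) / s_baseline`.
   A zero baseline SD is not patched with an epsilon — the cell is excluded
   with a warning, so degenerate (e.g. noiseless synthetic) inputs fail
   loudly rather than silently.
4. **Averaging**: epochs are averaged within condition, then the three
   condition curves are averaged into a grand average.
5. **Vectorization**: the grand-average standardized time courses are
   concatenated channel by channel (optionally downsampled; default every
   10th sample, i.e. 1 Hz effective) into one feature vector per subject.

Two orderings were genuinely open: whether standardization precedes
averaging, and whether PCA consumes grand averages or condition averages.
We standardize per epoch and then average (each epoch's baseline is the
natural reference for that epoch), and feed the grand average to PCA;
`order = "average_then_zscore"` and `mode = "condition"` expose the
alternatives.

## Feature engineering

Tabular (NPS/BIO) features are z-scored, `z = (x − m)/s`. The default
inside cross-validation takes `m`, `s` from the training fold only; a
`population` mode (whole-table statistics) is provided as an explicit
divergence switch because whole-cohort standardization, while sometimes
reported, leaks held-out information.

NIRS vectors are high-dimensional, so each training fold fits a PCA
(mean-centering only, no rescaling — the inputs are already in baseline-SD
units) yielding at most `N − 1` coefficients for `N` training subjects.
Coefficients are ranked by Fisher's discriminant ratio

$$\mathrm{FDR}_j = \frac{(\mu_{j,\mathrm{ADHD}} - \mu_{j,\mathrm{TD}})^2}
                        {\sigma^2_{j,\mathrm{ADHD}} + \sigma^2_{j,\mathrm{TD}}},$$

a univariate separability score (not the false-discovery rate), and the top
60% are retained. Retention uses the *ceiling* rule: `ceil(0.6 × 19) =
ceil(0.6 × 20) = 12`, so training folds of 20 or 21 subjects both keep 12
coefficients — the only rounding consistent with that count. Variances
throughout use the sample (`n − 1`) denominator; the formulas do not pin
the denominator down and the ratio is insensitive to the common factor.
Degenerate columns are ordered deterministically (zero variance with
distinct means → infinite score, ranked first; ties broken by original
index).

## Classification and the nested cross-validation

The classifier is a linear-kernel SVM with the regularization constant at
its conventional default (`C = 1`), never tuned — linear kernels are cheap
and leave no hyper-parameter search to bias the protocol. ADHD is the
positive class everywhere.

Feature-subset optimization is a *wrapper*: every non-empty subset of the
candidate features (`2^p − 1` of them: 1,023 for 10 BIO features, 4,095
for 12 retained NIRS coefficients, ~2.6 × 10^5 for 18 NPS features) is
scored by classifier accuracy, inside a nested 10-fold cross-validation:

* the cohort is split into 10 stratified subsets of near-equal size
  (`make_fold_plan()`: within-class shuffling, then dealing fold labels
  sequentially — sizes differ by at most one and both classes reach every
  training set);
* in each round, 9 subsets form the inner pool. The protocol for scoring a
  subset on that pool is stated only loosely in this design's sources, so
  we fixed it as 9-fold cross-validation over the inner subsets with pooled
  held-out accuracy: it uses all inner data, adds no randomness, and keeps
  the outer fold untouched;
* the best subset (ties broken toward smaller subsets, then
  lexicographically — the most parsimonious of the equally good) trains one
  SVM on the whole inner pool and is evaluated on the held-out subset;
* accuracy, sensitivity (ADHD true-positive rate) and specificity (TD
  true-negative rate) are computed per round and reported as mean ± SD
  across the 10 rounds — each subject is predicted exactly once.

For NIRS domains the *entire* engineering chain (centering, PCA, FDR,
retention) is refit inside every inner and outer training split; held-out
rows never touch a fitted artifact, and the test suite asserts
bit-identical transforms under perturbation of held-out rows. Because PCA
yields `N − 1` coefficients and `N` varies by one across splits, the
candidate count is harmonised to the minimum across a round's inner splits.

Feature importance is the occurrence frequency of each feature across the
10 round-optimal subsets (0–10); features never selected report 0.

## The ensemble

The domain models' pooled outer-fold predictions (on one shared fold plan)
are combined by majority vote. Five member combinations are evaluated by
default: the four three-member combinations of {NPS, BIO, NIRS_OXY,
NIRS_DEOXY} and the full four-member ensemble. Two quantities required
design decisions the sources leave open:

* a 2–2 tie in the four-member ensemble is resolved by the sum of the
  members' signed SVM decision margins; if margins are unavailable the tie
  goes to TD (the negative class) — a conservative, documented rule;
* members emit hard labels, so the ROC/AUC is computed on the discrete
  per-subject ADHD *vote count* (0..k) by rank-based (Wilcoxon)
  integration with ties contributing ½.

Ensemble metrics are fold-wise mean ± SD on the shared outer folds.

## The synthetic cohort generator

The original clinical cohort (22 ADHD, 22 TD children) is not publicly
deposited, so `simulate_cohort()` generates cohorts with the same design:
22 subjects per group, 18 NPS and 10 BIO features, 32 fNIRS channels, the
standard 750 s protocol. Defaults, chosen once as plausible for this kind
of data and documented here rather than tuned:

* **Tabular features**: unit-variance normals with group-mean shifts equal
  to per-feature Cohen's *d*. Defaults cycle strong/weak/null
  (`d = 0.8, 0.4, 0`) across NPS features; BIO features taper
  `0.8, 0.5, 0.3, …` with the last two null (mirroring markers that carry
  no group signal). An equicorrelation option exists (`feature_correlation`)
  but defaults to independent noise.
* **fNIRS signal**: boxcar task regressors scaled by a per-group,
  per-condition amplitude, convolved with a double-gamma hemodynamic
  kernel peaking near 5 s (any smooth positive kernel would do; this one is
  fixed and unit-sum so a sustained block plateaus at its amplitude), plus
  a per-channel gain (U(0.5, 1.5)), a linear drift (0.001 mM·mm/s) and
  i.i.d. Gaussian noise (SD 0.5 mM·mm). TD amplitudes rise with memory load
  (C 0.3, 1B 0.6, 2B 1.0); ADHD amplitudes are attenuated (0.3, 0.4, 0.5),
  so the groups differ in task-evoked response, not raw level. DEOXY is the
  OXY response scaled by −0.3 with independent noise — anticorrelated and
  smaller, echoing the physiological contrast, without claiming a
  physiological model.
* The sampling rate is not a protocol constant; the default is 5 Hz.

What the generator does *not* emulate: optical-density physics and the
modified Beer–Lambert conversion (signals are generated directly as
hemoglobin concentration change), motion artifacts, systemic physiology
(cardiac, Mayer waves), spatial channel correlation, non-Gaussian tails,
and realistic inter-feature correlation structure in the tabular domains.
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* is correct and calibrated — not that real clinical data would
reach any particular accuracy. Under the default separations the synthetic
NIRS domains are considerably cleaner than real recordings, and
classification accuracies near the ceiling are expected and not a claim
about clinical performance.

## Numerical and runtime choices

* Exhaustive search cost grows as `2^p`; the full 18-feature NPS search
  (~2.6 × 10^5 subsets, each scored by 9 inner fits) is an hours-scale run.
  `classify_cohort()` and the CLI therefore expose runtime guards
  (`max_features` for the NIRS retention cap, `max_tabular_features` for
  NPS/BIO truncation); `enumerate_subsets()` refuses `p > 25` without
  `force`. The bundled tests and the acceptance script run wrapper
  searches with 3–10 candidates and cohorts of 12–44 subjects, sizes at
  which the whole suite completes in minutes.
* Calibration checks in the test suite: on null cohorts (all `d = 0`,
  22 + 22) the mean nested-CV accuracy stays within a chance envelope of
  [0.30, 0.70] over 10 generator seeds, and with five `d = 3` features the
  mean accuracy exceeds 0.90 — the wrapper's selection optimism stays in
  the inner loop where it belongs.
* All randomness (cohort generation, fold plans) flows from explicit
  integer seeds; given a seed and a configuration, every output is
  bit-reproducible. SVM fitting and the wrapper search are deterministic.

## Known limitations

* The exhaustive wrapper is faithful to the design but does not scale past
  ~20 candidate features; no greedy fallback is provided because heuristic
  search would change the method.
* Sensitivity/specificity are undefined on outer folds lacking a class;
  such folds are excluded from the affected mean (the stratified plan makes
  this rare at 22 + 22, but small cohorts with many folds can trigger it).
* The vote-count AUC is a coarse, discrete ROC; with three members it has
  only four score levels.
* Synthetic fidelity limits are listed above; no claim transfers from
  synthetic to clinical accuracy.
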