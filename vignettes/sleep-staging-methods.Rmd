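---
title: "Sleep staging from wearable sensors: models, features and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from wearable sensors: models, features and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SomnoStage)
```

## The problem

Polysomnography (PSG) is the reference standard for sleep staging but is
expensive, obtrusive and impractical for long-term monitoring. Chest- and
finger-worn sensor systems record ECG, triaxial acceleration, oxygen
saturation and skin temperature unobtrusively; the question is how much of
the 30-s-epoch AASM hypnogram (Wake, N1, N2, N3, REM) can be recovered from
those streams alone, and whether a classifier trained on *other people*
(a population model, evaluated by leave-one-subject-out cross-validation)
can compete with one trained on *the same person's* night (a personal
model, evaluated by stratified 10-fold cross-validation).

SomnoStage implements that entire analysis as a tested pipeline. Because
overnight inpatient recordings are not distributable, the package includes
a first-class synthetic-data module that generates multichannel nights with
known ground truth, so every downstream stage — filtering, R-peak
detection, synchronization, feature extraction, model selection, metrics —
is verifiable against known-by-construction answers.

## The synthetic generator

`generateHypnogram()` draws stage sequences from a first-order Markov chain
at 30-s resolution (the minimal structure that produces realistic stage
bouts), starting in Wake at bedtime. The default transition matrix yields
nights that are roughly 15% Wake, 55% N2/N1, 15% N3 and 12% REM in the
long run, with consolidated bouts of deep sleep and REM.

`generateRecording()` renders eight channels at their nominal rates (ECG
512 Hz, x/y acceleration 52 Hz, z acceleration 416 Hz, SpO2 5 Hz,
temperatures and device heart rate 1 Hz):

* **ECG** — a fixed QRS template placed at R-times from a stage-dependent
  point process. Mean interval is `60000 / HR(stage)` ms; beat-to-beat
  variability is a two-band oscillation (0.1 Hz "LF" and 0.25 Hz "HF")
  carrying 85% of the stage's SDNN variance — split per stage between the
  bands — plus white jitter for the remainder. Deep sleep is slow with a
  high HF share; Wake and REM are fast with LF dominance, so
  frequency-domain HRV features separate stages by construction.
  Morphological realism is out of scope: only R-time geometry matters
  downstream, and the true R-times are retained for validation.
* **SpO2** — a ~97% baseline with desaturation events from an exponential
  inter-arrival process (default 6/h, 6 percentage points deep, 25 s,
  trapezoidal profile), which makes the ODI/TSA features countable against
  known truth.
* **Acceleration** — gravity-oriented quiet baselines with 2-s movement
  bursts at stage-dependent rates, concentrated in Wake.
* **Temperature** — chest and limb baselines with a distal rise during
  sleep (default +1.5 °C, smoothed over ~5 min), reproducing the
  distal-to-proximal-gradient (DPG) increase that accompanies sleep-related
  vasodilation.

Defaults were chosen once as physiologically plausible values for an adult
inpatient cohort (e.g. Wake 78 bpm → N3 56 bpm; SDNN 25–55 ms) and are not
tuned to any test outcome. `generateCohort()` adds between-subject
heterogeneity on two levels: additive baseline offsets on HR, SpO2 and
temperature, and — because within-subject z-scoring would erase purely
additive offsets — proportional perturbations of the stage-dependent
*contrasts* themselves (per-stage HR means, HF/LF balance, movement rates,
DPG shift). At heterogeneity 0 all subjects share identical physiology; at
high heterogeneity the feature-to-stage mapping differs across subjects,
which is precisely the regime in which personal models should beat a
population model. The default cohort is nine subjects of ~5.4 h each,
matching the usable-data scale of a small inpatient study. At extreme
heterogeneity a drawn subject's baseline heart rate can sit near the
40 bpm validity threshold, in which case most or all of that subject's
epochs are screened out and the subject effectively drops from the
analysis — the synthetic analogue of excluding an unusable recording;
`buildFeatureTable()` logs this and carries on with the remaining
subjects.

What the generator does **not** emulate: real QRS morphology and ectopy,
PPG waveforms (SpO2 is synthesized directly), respiration, sensor
detachment artifacts, and circadian trends beyond a slow temperature
drift. Passing tests therefore demonstrate correctness of the pipeline's
mechanics and its behavior under controlled physiology — not clinical
performance on real patients.

## Preprocessing

* Channels are resampled to nominal rates by polyphase band-limited
  interpolation; the z-axis accelerometer (416 Hz) is decimated to the
  common 52 Hz grid before statistics.
* Accelerometer and ECG streams are highpass filtered with a fifth-order
  Butterworth at 1 Hz, applied forward–backward (zero phase) so R-peak
  timing is preserved. The filter runs as a cascade of second-order
  sections: with the cutoff far below Nyquist, the single
  transfer-function form is numerically ill-conditioned. Signals are
  odd-reflection padded (10 cutoff time constants) so edge transients stay
  out of the analyzed samples.
* Two independently clocked recordings are aligned by cross-correlating
  their ECG channels (`synchronizeByEcg()`), both resampled to a common
  128 Hz — adequate for QRS alignment at low cost — within a ±300 s
  default search window. Positive lag means the target starts later.
* The physiological validity screen drops any epoch with minimum SpO2
  below 50% or minimum heart rate below 40 bpm ("less than" is strict);
  such values indicate poor sensor contact rather than physiology. The
  screen takes HR from the detected R-R series (60000 / max RR in the
  epoch) and falls back to the 1 Hz device channel when fewer than two
  beats were detected.

## R-peak detection

`detectRPeaks()` implements the classic Pan-Tompkins stages: 5–15 Hz
bandpass, five-point derivative, squaring, 150 ms moving-window
integration, adaptive dual thresholds with a 200 ms refractory period and
a search-back pass at 1.66× the running R-R average, with constants from
the original description. Two implementation choices matter:

* candidate integration-signal maxima are consolidated by
  amplitude-ordered suppression within the refractory distance, so noise
  ripples on a QRS energy bump cannot pre-empt its true maximum;
* each accepted fiducial is localized to the signal maximum within
  ±50 ms, giving millisecond-level timing on clean signals.

R-R intervals outside [300, 2000] ms are treated as implausible (missed or
spurious beats) and dropped before feature computation.

## The 73 epoch features

Features are computed on non-overlapping 30-s epochs: 33 accelerometer
(9 statistics × 3 axes + 3 inter-axis Pearson correlations with
p-values), 19 ECG (R-R and heart-rate summaries, SDNN, RMSSD, NN/PNN at
20 and 50 ms with strict inequality, and FFT band powers/peaks for VLF
0.0033–0.04 Hz, LF 0.04–0.15 Hz, HF 0.15–0.4 Hz plus the LF/HF ratio),
6 temperature (DPG mean/min/max/range and the two channel means) and 15
oximetry (moments, lag-1 autocorrelation, zero-crossing rate, the mean
absolute difference between successive 10-s window means, TSA at
95/90/85/80/70% and ODI at 2–5 points).

Numerical conventions, stated so tests can be exact: population (n)
variance and SD; Pearson (non-excess) kurtosis, set to 0 on a constant
axis; correlations involving a constant axis get rho 0 and p 1 so the row
stays valid; LF/HF uses a `LF/(HF + 1e-12)` guard. The R-R tachogram is
linearly interpolated to 4 Hz over the epoch, mean-removed and zero-padded
to 4096 points before the periodogram; on a 30-s window the VLF band spans
barely one cycle, so the VLF features are near-degenerate and carried for
completeness only.

Two definitions in this feature set are genuinely underdetermined and were
fixed as follows:

* **SpO2 rho** is the lag-1 autocorrelation of the epoch's samples — a
  within-epoch self-similarity measure that keeps the 15-feature oximetry
  count.
* **ODI events** are maximal sample runs at least 2 points (the shallowest
  reported threshold) below the previous valid epoch's mean; ODIx counts
  the events whose depth reaches x points. Counting runs separately per
  threshold would violate the natural ordering ODI5 ≤ ODI4 ≤ ODI3 ≤ ODI2
  whenever noise ripples inside a deep dip; classifying events by depth
  preserves it by construction and agrees with event counting as
  practiced in oximetry.

Epochs with fewer than three usable R-R intervals, a missing channel, or a
failed validity screen are excluded; every exclusion is tallied with a
reason in `metadata(table)$excluded`, so input epochs always equal used
plus excluded.

## Modeling

`modelSpec()` pairs each algorithm with its imbalance strategy: class
weights plus random undersampling for balanced bagging and balanced random
forest (ranger backend; bagging sets mtry to the full feature count), and
SMOTE (k = 5 same-class nearest-neighbour interpolation, seeded; a
single-member class falls back to random oversampling) for gradient
boosting and XGBoost (xgboost backend; the gradient-boosting variant uses
exact greedy splits with zero regularization, the classic GBM recipe).

`nestedCV()` evaluates under two frameworks. Population: outer
leave-one-subject-out folds. Personal: stratified 10-fold outer CV on one
subject's night (random stratification; temporal blocking would be the
conservative alternative and is deliberately not the default, matching
per-epoch evaluation practice). Within every outer training set:

1. correlation pruning — greedy scan in the fixed column order dropping
   any feature whose |r| with an already-kept feature exceeds 0.95
   (strictly);
2. recursive feature elimination — the algorithm's own importances
   (impurity for forests, gain for boosting) rank features; halving steps
   build a nested ladder down to 8 features;
3. an inner stratified 10-fold grid search over the hyperparameter grid ×
   the ladder, scored by support-weighted F1 averaged over inner folds
   (ties prefer fewer features, then earlier grid rows);
4. the best configuration is refit with rebalancing on the full outer
   training set and applied once to the held-out fold.

Rebalancing touches training folds only — never test folds. Within-subject
z-scoring uses each subject's full night even in the population framework:
normalization is defined per subject, not per fold. This mirrors how
per-subject normalization is commonly applied, and it carries a known
mild leakage caveat (the test subject's own night statistics standardize
their features); it also makes features sensitive to a night's stage
*composition* — a subject who sleeps nearly the whole night has a lower
night-mean heart rate, which shifts their z-scored wake epochs. That
composition effect is the main reason population kappa varies across
synthetic cohort draws even at heterogeneity 0.

Default grids are deliberately desk-scale: trees {100, 300}, depth
{3, 6}, plus learning rate {0.05, 0.1} for the boosting variants. All
randomness (fold assignment, undersampling, SMOTE, tree seeds) derives
from the `ModelSpec` seed, so a `CVResult` is reproducible end to end. The inner
rebalancing happens inside each inner training split, after pruning and
normalization.

## Evaluation

Agreement is summarized by a **pooled** Cohen's kappa: one confusion
matrix aggregated over all test folds, `kappa = (p_o − p_e) / (1 − p_e)`
with chance agreement from the pooled marginals. Pooling rather than
averaging avoids inflating the estimate's variance around mid-range kappa
values. Qualitative bands: <0 worse-than-chance, 0–0.20 slight, 0.21–0.40
fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1 near-perfect
(boundaries belong to the lower band).

`perClassMetrics()` reports one-vs-rest specificity, precision,
sensitivity and F1 (`F_beta` with beta = 1; an empty predicted class gets
precision 0, flagged), balanced accuracy as the arithmetic mean of
per-class sensitivity, and per-fold mean ± SEM for table-style reporting.
Micro-averaged recall equals overall accuracy and is asserted on every
report. `sleepArchitecture()` computes total sleep time (0.5 min per
non-Wake epoch), stage percentages of total recording time (applied
uniformly to all stages), and awakenings as maximal Wake runs strictly
inside the sleep period — after the first and before the last non-Wake
epoch — since an undefined "awakening" is most conservatively read as an
interruption of established sleep.

`tsneEmbedding()` is an exact t-SNE (perplexity calibration by bisection,
early exaggeration, momentum gradient descent) with the defaults used for
feature-space visualization here: perplexity 40, 300 iterations. It exists
in-package because no t-SNE implementation is available in the supporting
libraries; it is O(n²) and intended for cohort-scale epoch counts (a few
thousand rows). When rows < 3 × perplexity + 1 the perplexity shrinks with
a warning.

## Problem sizes used in the tests

The test suite and the acceptance script size their simulations for a
single CPU: most fixtures are 0.25–0.5 h nights; the cohort experiments
use 5 subjects × 2 h (1200 epochs) with a balanced random forest and a
{100, 300}-tree grid, which keeps the full nested CV — 10 inner folds,
RFE ladder and all — at a few minutes per framework while leaving the
methodology intact. Oracle-equivalence checks run ~1000 randomized small
inputs per statistic against naive loop implementations.

## Known limitations

* Synthetic physiology is stylized; absolute performance numbers on it do
  not transfer to real patients.
* VLF features on 30-s epochs are near-degenerate (one cycle per window).
* Per-subject full-night normalization leaks night-level statistics into
  held-out epochs (inherent to the chosen normalization) and couples
  features to stage composition.
* The personal framework's random stratified folds place temporally
  adjacent epochs in train and test; temporal blocking would give more
  conservative estimates.
* t-SNE is exact (no Barnes-Hut); embeddings beyond ~5000 rows are slow.
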