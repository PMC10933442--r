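---
title: "Arousal intensity scoring and per-stage classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arousal intensity scoring and per-stage classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arousalint)
```

This vignette explains the models and procedures `arousalint` implements,
the assumptions behind them, the tunable parameters and their defaults, and
the design choices made where the method leaves room for interpretation.
Everything empirical stated here is computed by the package's test suite or
by `scripts/acceptance.R`; nothing is quoted from external runs.

## 1. The intensity score

An arousal is an abrupt EEG shift to higher frequency lasting at least 3 s,
preceded by at least 10 s of stable sleep. Its *intensity* is defined here
as the amplitude distance: the mean over the two central EEG channels of
the peak-to-peak amplitude inside the event window,

$$A \;=\; \tfrac12\!\left[(\max_{t} C3 - \min_{t} C3) + (\max_{t} C4 - \min_{t} C4)\right],
\qquad t \in [\text{onset},\, \text{onset}+\text{duration}).$$

Amplitudes are measured on the *preprocessed* signal (high-passed,
resampled; Section 3). Whether a raw or conditioned signal is meant by the
method description is not fixed anywhere; measuring after conditioning
makes the score robust to drift and is the package default — the scoring
function accepts any recording, so the alternative is one call away.

Scores are binned into levels 1–4 at the 25th/50th/75th percentiles of the
non-sham amplitude distribution (linear-interpolation quantiles, the common
default estimator; `type = 7` in R's `quantile`). Intervals are
right-closed, `(q_{k-1}, q_k] -> k`, and the outer edges extend slightly
past the observed range so every fitted value lands in a level; out-of-range
amplitudes (possible only with *fixed* thresholds) clamp to 1 or 4 with a
warning. Two threshold modes exist because quartiles are cohort-specific:
`fit` (default) recomputes them from the data at hand; `fixed` applies the
reference edges shipped in `inst/extdata/reference_thresholds.json`
(9.3e-5 / 1.64e-4 / 4.04e-4 V, with sentinels −1e-3 and 6.03e-3 V). The
negative lower sentinel is impossible for a peak-to-peak range and is kept
as an open lower bound, as standard quantile binning produces.

**Sham arousals.** As level-0 controls, 10–14 windows (count drawn
uniformly) of 9 s of stable sleep are selected per recording. "Stable
sleep" is operationalized as: entirely within non-wake epochs, at least
10 s from every arousal boundary (mirroring the stability requirement in
the arousal definition) and from every other sham window. Each sham window
uses the 9 s immediately before it as its pre-window, for symmetry with
real events.

## 2. Synthetic polysomnography

The generator replaces restricted clinical data with recordings that have
exactly the statistical structure the pipeline relies on:

* **Hypnogram** — first-order Markov chain over {W, N1, N2, N3, REM} in
  30-s epochs, starting in wake. The default transition matrix yields
  N2-dominant sleep with regular N3 and REM episodes.
* **Background EEG** — per channel, a sum of band-limited Gaussian noise
  components (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 Hz) with
  stage-specific weights, scaled to a stage RMS: N3 delta-heavy and largest
  (14 µV), REM low-voltage mixed-frequency (7 µV), others ~9–10 µV. The RMS
  levels sit well below the event amplitude scale so that the measured
  peak-to-peak of an event window is dominated by the injected burst —
  the regime in which quartile edges near 1e-4 V are meaningful. (The
  window range of the background itself is ~5–10e-5 V and enters every
  measurement as a noise floor.)
* **Arousal bursts** — additive 8–30 Hz filtered-noise bursts with 0.5-s
  raised-cosine ramps, matching "abrupt shift to higher frequency" without
  modelling waveform morphology no downstream computation inspects. Each
  EEG channel's burst is scaled so its peak-to-peak equals the drawn
  amplitude exactly; the chin EMG burst is injected at half scale.
* **Amplitudes and strata** — amplitudes follow a log-normal law (default
  median 1.8e-4 V, σ_log 0.9, the order of magnitude of the reference
  thresholds). Ground-truth strata are the law's quartile cells. Stratum
  labels are assigned *balanced* per recording (shuffled round-robin, random
  remainder) rather than i.i.d., so empirical quartiles of a desk-scale
  sample fall into the gaps between strata instead of inside them. The
  `class_separation` multiplier compresses each event's within-stratum
  sub-quantile toward the stratum-center quantile by `1/class_separation`:
  1 reproduces the plain law, large values make the four strata essentially
  disjoint — the premise of the recovery tests.
* **Placement** — seeded rejection sampling under the event constraints
  (≥ 3 s duration, ≥ 10 s of non-wake event-free signal before onset,
  pre-window inside the recording, no overlaps). If the requested rate
  cannot be met, fewer events are emitted with a warning.

What the generator does **not** emulate: spindles, K-complexes, artifacts,
inter-subject variability, apnea physiology, or any coupling between stage
and arousal amplitude. Passing recovery tests therefore demonstrate that
the pipeline's machinery is correct and leak-free — not that the clinical
classification performance would be reproduced on real EEG.

## 3. Preprocessing

Order: high-pass at the native rate, then resample, then segment.

* **High-pass, 0.3 Hz.** The nominal design is a 4th-order Butterworth
  applied forward-backward (zero phase). At a normalized cutoff of
  0.3/100, time-domain recursions are numerically treacherous: the standard
  transfer-function implementation available here leaks half the DC level
  through, and any causal forward-backward pass drags multi-second edge
  transients into the record. The package therefore applies the *exact*
  zero-phase Butterworth magnitude response, `|H(f)|² = 1/(1+(f_c/f)^8)`,
  spectrally: identical nominal response, exact DC zero, no transients,
  and idempotent wherever `|H|² ≈ |H|⁴` (verified to ~1e-11 on passband
  content in the tests).
* **Resampling 200 → 128 Hz.** Also spectral: the spectrum below the
  smaller Nyquist frequency is kept bin-for-bin (sample counts map by
  16/25). This is inherently anti-aliased and introduces no group delay,
  so event timestamps remain aligned with the signal — the polyphase
  resampler available here leaves an uncompensated ~3-sample delay, which
  would shift every segment window. Resampling to the native rate is the
  identity; repeating a resample is exactly idempotent.
* **Segments.** Windows are half-open `[onset, onset+duration)` in seconds
  from recording start; sample indices are `round(t · fs)`. The pre-window
  is the equally long interval before onset; events without room for it
  are skipped and logged. Composite signals "C3/4", "O1/2", "F3/4" are
  sample-wise channel means (the montage is not specified anywhere; the
  composite map is configurable), and the chin EMG passes through and
  receives identical preprocessing.

## 4. Features (132 + 4)

Each segment is decomposed with a 5-level discrete wavelet transform,
Daubechies order 4, periodization boundary mode. At 128 Hz the detail sets
D1–D5 cover 32–64, 16–32, 8–16, 4–8, 2–4 Hz and A5 the 0–2 Hz residue. The
transform is implemented in the package (no wavelet package exists in the
dependency environment) as circular convolution with the orthonormal db4
filter pair; orthonormality gives exact energy conservation for lengths
divisible by 2⁵ (tested to 1e-8 relative on random signals), and odd
intermediate lengths are edge-padded as PyWavelets does. The minimum
segment length is 32 samples (0.25 s at 128 Hz; real events are ≥ 3 s).

Per signal and coefficient set: mean power (mean squared coefficient), MABS
(mean absolute coefficient), variance; plus the 15 MABS ratios over
unordered set pairs with the finer set in the numerator (D1/D2, D1/D3, …,
D5/A5). That is 6+6+15+6 = 33 per signal and 132 over the four signals —
the only reading of the published feature census consistent with
4 × (6+6+15+6); a per-signal "total variance" (28 features) or ordered
ratio pairs (30 per signal) would contradict it. Four auxiliary features on
C3/4 complete the vector: PSI (mean over the five default bands 0.5–4,
4–8, 8–13, 13–30, 30–60 Hz — clipped at Nyquist — of summed periodogram
power in band; the band set is configurable, none being prescribed),
average power, RMS, and the DFA exponent α (first-order DFA, windows
log-spaced in [4, N/4], least-squares slope of log F(n) vs log n; ≈ 0.5
for white noise and ≈ 1.5 for integrated noise, verified by simulation).
"Average" PSI/power/RMS/DFA is computed once over the whole segment; the
sub-window-averaging alternative reading is noted but not taken.

Every feature is normalized as arousal value / pre-arousal value. The four
auxiliary features are normalized too, although the published phrasing
binds "all those features" only to the 132 — consistency of the feature
space argues for normalizing everything, and the option `normalize_aux`
would be a one-line change. Denominators are floored at ε = 1e-24 with a
logged flag. An ε of 1e-12 was considered and rejected: with signals in
volts, squared-coefficient features of quiet channels are genuinely
1e-12–1e-16 V², so such a floor would silently corrupt real features and
break scale invariance of the ratios (multiplying both segments by k > 0
must leave all 132 wavelet ratios unchanged — a tested property). 1e-24
lies far below any representable feature magnitude and still guards exact
zeros. Events yielding non-finite features after the guard are dropped and
enumerated in a drop log.

## 5. Stage models

* **Split.** One global 80/20 split (test size `ceiling(0.2 N)`),
  stratified by intensity level with per-level quotas by largest remainder,
  then partitioned by the sleep stage at event onset into four stage
  datasets. Stratification is not part of the original description but
  stabilizes desk-scale runs; the published size arithmetic
  (14,512 → 2,903 / 11,609) is reproduced exactly.
* **SMOTE** (training data only, never test rows — an event-id audit in the
  tests enforces this). All minority levels are raised to the majority
  count; each synthetic row is `x + u(neighbour − x)`, `u ~ U(0,1)`, with a
  uniformly drawn one of the `k = 5` nearest same-class neighbours.
  Whether balancing preceded or followed the original split is unstated;
  applying it strictly after, to training data only, is the only
  leakage-free reading. RFE runs on the balanced data (also unstated;
  balanced is the default here).
* **RFE-CV.** From all 136 features, iteratively: measure mean stratified
  5-fold CV accuracy, refit on the full training data, drop the least
  important 20% of features (impurity importance for the forest, gain for
  boosting; `step` is configurable down to one-at-a-time). The subset with
  the highest mean CV accuracy along the path wins; ties prefer the
  smaller subset. Both classifier families are evaluated per stage and the
  better one kept (ties prefer the random forest).
* **Classifier families.** Random forest (`ranger`, single-threaded for
  determinism) and gradient boosting (`xgboost`, the gradient-boosting
  implementation available in the dependency environment). Search spaces:
  forest — trees 100–400, depth 4–24, min leaf 1–10, feature fraction
  0.1–0.9; boosting — rounds 50–300, learning rate 0.02–0.3 (log), depth
  3–10, min child weight 1–10, column fraction 0.3–1. The boosting default
  `min_child_samples` is 1 because multiclass soft-prob hessians make
  larger values behave like ~4× larger leaf minima.
* **TPE tuning with successive halving.** The tuner is implemented in the
  package: after a random startup phase, candidates are drawn from a
  Parzen (Gaussian-mixture) density over the best γ = 25% of trials and
  ranked by the good/bad density ratio; trials are evaluated fold-by-fold
  and pruned at rungs 1, ⌈K/2⌉, K when their running mean falls below the
  median of peers (successive halving). For small finite spaces,
  already-evaluated configurations are never revisited, so the search
  degenerates gracefully to exhaustive enumeration (a test pins the tuner
  to the brute-force optimum of a deterministic quadratic over a 20-point
  grid). The tuning objective defaults to mean CV accuracy;
  `level0_sensitivity` is offered because the original optimization is
  described as driven by sham-detection sensitivity, and which quantity
  was literally optimized is ambiguous. Default budget: 30 trials
  (10 in the acceptance run).
* **Degenerate stages.** A stage whose training set lacks a level simply
  omits it from the label set; stages with fewer than `min_stage_rows`
  (default 20) training rows, or no test rows, are skipped with a warning.

## 6. Evaluation and aggregation

Per stage and level (one-vs-rest): sensitivity, specificity, PPV, NPV from
the confusion matrix — undefined 0/0 ratios are reported absent (`NA`),
never as 0 — and AUROC by the rank statistic with half credit for ties
(equal to the exhaustive positive–negative pair count, and invariant under
strictly increasing score transforms; both tested, plus a cross-check
against `pROC`).

The cross-stage **average** for a level is the *unweighted* mean over the
stages whose test set contains that level — the only rule consistent with
the published worked example (82.22, 80.56, 86.42 averaging to 83.07 with
the level absent from the fourth stage); support-weighting does not
reproduce it. The **total** row pools all stage predictions, computes
per-level metrics on the pool, and reports their support-weighted means.
(The published text also quotes one sham-AUROC average, 97.07, that is
inconsistent with its own table under either rule; the table rule is
implemented.)

## 7. Problem sizes and reproducibility

Every stochastic step takes a seed derived from one global seed: the same
configuration and seed reproduce byte-identical artifacts (tested on the
report JSON). The test suite runs at desk scale: the end-to-end recovery
uses 8 one-hour recordings at 36 arousals/hour with `class_separation = 8`
and 10 tuning trials (~290 arousals + ~95 shams, ~77 held-out events,
about two minutes on one CPU). One hour rather than a shorter recording
was chosen so each level keeps ≥ 14 held-out events — with fewer, a single
quartile-boundary event swings a per-level sensitivity by ~15% and the
macro average measures sampling noise, not the pipeline. Under these
conditions the pipeline attains perfect or near-perfect held-out
sensitivity; the acceptance script prints the exact values it computes.

## 8. Known limitations

* The intensity score is a pure amplitude measure; time-frequency content
  does not enter the level definition (a stated limitation of the method
  itself).
* The visual 0–9 intensity scale of earlier work, arousal *detection*,
  additional classifier families, and subject-wise (leave-one-subject-out)
  validation are out of scope.
* Reference thresholds are cohort-specific; `fit` mode is the default for
  a reason.
* Synthetic recovery results bound what the tests can show about clinical
  data (Section 2).
* The EDF layer covers plain 16-bit continuous EDF (the subset the
  pipeline writes and reads); EDF+ annotation streams and vendor formats
  are not parsed.
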