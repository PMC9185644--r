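---
title: "Recognizing wheelchair propulsion gestures from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing wheelchair propulsion gestures from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In manual wheelchair dance, propulsions play the role that steps play for
a standing dancer: a choreography prescribes how many there are, when each
one starts, and how long it lasts. Assessing a dancer therefore requires
counting propulsion gestures and timing them, online, from unobtrusive
sensors. `propulse` implements a complete pipeline for this task from two
hand-worn inertial measurement units (IMUs) sampled at 30 Hz, optionally
complemented by a trunk sensor.

Eight specific propulsion gestures (PGs) are recognized: left-forward,
left-backward, right-forward, right-backward, forward, backward, clockwise
and anticlockwise rotation. Each is a bilateral combination of two basic
per-arm strokes, so the pipeline never classifies the eight gestures
directly. Instead, two *side classifiers* (left and right) each solve a
three-class problem — forward, backward, dance — over sliding windows, and
a deterministic 3×3 fusion table rebuilds the specific gesture from the
label pair. Everything that is not a propulsion is "dance" (DG), including
*fake propulsion gestures* (FPGs): movements that mimic a propulsion
kinematically but never touch the hand rim.

During data acquisition a force-sensitive resistor (FSR) in each palm logs
hand–rim contact. The FSR is used **only for labeling**: contact-interval
boundaries segment the training data semi-automatically and provide the
reference onsets/durations for evaluation. The deployed system uses IMUs
only.

## Pipeline

1. **Windowing.** A trial of `n` samples is cut into
   `m = floor((n - w)/s) + 1` half-open windows of `w` samples advanced by
   `s`; window `k` covers samples `[k·s, k·s + w)`. Tail samples that do
   not fill a window are dropped.
2. **Labeling** (training only). A window inherits a propulsion label when
   it fully contains the gesture, when the gesture fully contains it, or
   when at least 70% of its samples fall inside the gesture (inclusive
   threshold — "at least 70%" — measured in samples against the window
   size, since the rule is tied to the window, not the gesture). All other
   windows are dance. A window qualifying for two different propulsions is
   a labeling conflict and raises an error rather than being silently
   resolved; the standard choreography structure cannot produce one.
3. **Features.** Per side, 8 input signals in two-sensor mode (hand
   accelerometer X/Y/Z, gyroscope X/Y/Z, and the per-sample Euclidean
   norms |a| and |ω|) or 10 in three-sensor mode (plus trunk accelerometer
   Z and trunk gyroscope). Each signal yields 13 time-domain features on
   the raw window and 6 frequency-domain features on a causally filtered
   copy — 19 per signal, hence 152 features (8×19) or 190 (10×19).
4. **Training.** Univariate ANOVA-F feature selection to at most
   `nf_max = 30` features, then an exhaustive grid search (SVM, kNN,
   random forest) with seeded stratified 10-fold cross-validation; the
   best algorithm/hyperparameter combination is refitted on the full
   balanced dataset. The dance class is randomly undersampled to
   `max(#forward, #backward)` beforehand.
5. **Fusion and events.** At inference every window's label is painted
   onto its newest samples, the two side streams are fused pairwise
   ((F,D) → left-forward, (F,F) → forward, (F,B) → clockwise, ..., (D,D) →
   dance), non-dance segments shorter than 50 ms are relabeled dance
   ("spike filter"), and each maximal remaining non-dance segment becomes
   one propulsion event with an onset and a duration.

```{r}
library(propulse)
corpus <- simulate_corpus(n_subjects = 8, trials_per_subject = 10, seed = 42)
right <- train_side(corpus, "right", params = window_params(30, 5))
left  <- train_side(corpus, "left",  params = window_params(30, 5))
res <- recognize_trial(corpus[[1]]$recording, left, right, step = 1)
score_timing(res$events,
             subset(corpus[[1]]$annotations, fsr_active))
```

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fs_hz` | 30 | Hz | Hand-gesture content lives below ~10 Hz; 30 Hz covers it for 17 multiplexed channels. |
| `w` | 30 | samples | One second of context; the best accuracy in the window sweep. `w = 10` is the *timing* configuration (see latency below). |
| `s` | 5 | samples | Training stride; window sweep evaluates `w ∈ {10,20,30} × s ∈ {3,5}`. |
| `min_overlap` | 0.7 | fraction of `w` | The labeling rule's partial-overlap threshold, inclusive. |
| filter | order 2, 4 Hz low-pass Butterworth | — | Isolates the gesture band before spectral features; applied causally (forward only, zero state per window) because an online system cannot see future samples. |
| `nf_max` | 30 | features | Keeps accuracy within a few points of the full feature set while cutting the per-window cost five-fold. |
| `n_folds` | 10 | — | Cross-validation folds, stratified and seeded. |
| despike `min_ms` | 50 | ms | Fused gesture segments shorter than this are classifier confusions. |
| inference `step` | model's `s` | samples | `step = 1` re-classifies at every sample — the truly online regime, and the one in which a 50 ms filter has sub-step confusions to remove (at `s = 5`/30 Hz the minimum segment is 167 ms and the filter is vacuous). |

## Numerical definitions

* **Zero crossings** are strict sign changes of the *mean-centered* series
  (raw accelerometer channels carry the +9.81 m/s² gravity offset and
  would otherwise never cross zero); exact zeros are skipped.
* **Peaks** (time and frequency domain) are strict local maxima
  `x[i-1] < x[i] > x[i+1]` — the simplest operator consistent with both
  uses of the feature.
* **Kurtosis/skewness** use population moments (`m4/m2² − 3`,
  `m3/m2^1.5`) and are defined as 0 for zero-variance input; percentiles
  use linear interpolation (type 7).
* **PSD** is the one-sided periodogram `|FFT|²/n` of the filtered,
  mean-removed window, DC excluded, without Welch averaging (windows are
  at most a few dozen samples). **Spectral entropy** is `−Σ p log p` with
  the PSD normalized to unit mass, 0 for an all-zero series; its maximum
  is `log B` over `B` bins.
* Time-domain features are computed on the **unfiltered** window — the
  low-pass filter is scoped to the frequency-domain features only.
* An all-constant window is legal everywhere: dispersion features are 0,
  spectral features 0.

## Design choices in the open

* **Trunk gyroscope axis.** The recording schema stores a single
  `trunk_gyro` channel. Which physical axis it carries (the mediolateral
  bend axis or the yaw axis) is a mounting convention; the classifiers are
  agnostic to the name, and the simulator writes the yaw-like response
  there because turns are the only trunk-rotation cue it models.
* **Selection inside folds.** The feature selector is refitted inside
  every training fold by default, so the validation folds never influence
  the selected subset (`select_in_fold = FALSE` reproduces the optimistic
  variant that selects once on everything).
* **Grouped folds.** Overlapping windows of one propulsion are
  near-duplicates. With `group_by_trial = TRUE` (default) all windows of a
  trial share a fold, so reported CV is not inflated by twin windows
  straddling the split; pooled CV (`group_by_trial = FALSE`) is also
  available and is what the headline accuracies use.
* **Random-forest criterion.** The tuning grid carries
  `criterion ∈ {gini, entropy}` for interface compatibility, but the
  backend (`ranger`) implements the Gini impurity only, so both values
  produce identical fits; `max_features = "auto"` is mapped to `"sqrt"`.
  The kNN `algorithm` axis (ball tree / kd tree / brute / auto) selects a
  neighbor-search strategy and cannot change predictions of the exact
  search used here.
* **kNN.** Written in-package (standardized Euclidean distances, uniform
  or inverse-distance vote, deterministic tie-breaks) because no installed
  backend offers distance weighting.
* **Overall accuracy** is reported as the product of the two side CV
  accuracies. This assumes side errors are independent; correlated errors
  (both sides confused by the same movement) make it conservative.
* **Grid-search determinism.** Ties in CV accuracy are broken by the
  lexicographic parameter string, so the winner does not depend on grid
  row order; all forests are seeded and single-threaded.

## Detection latency: why there is a timing configuration

The 70% labeling rule teaches the classifiers to call a window
"propulsion" roughly when `0.7·w` of its samples overlap the gesture.
Painting each decision onto the window's newest samples is causal, so the
first propulsion-labeled span trails the true (FSR) onset by about
`(0.7·w − s)` samples. At `w = 30, s = 5` and 30 Hz that is a ~530 ms
floor — independent of classifier quality — and the measured onset MAE at
that configuration is ~540–610 ms. At `w = 10` the floor drops to ~67 ms
and the measured MAE is ~100–130 ms, comfortably inside the propulsion
timescale (~1 s). The same arithmetic applied to gesture offsets explains
why durations are systematically *under*-estimated by a causal
painter: both ends of the event are eroded by the threshold. The package
therefore documents two operating points: `w = 30` for recognition
robustness (including fake-propulsion rejection) and `w = 10` for onset
timing; `paint = "full-window"` trades causality for lower latency if a
single configuration is required.

## What the simulator emulates — and what it does not

The authors' human recordings are private, so `simulate_corpus()` stands
in for them. It reproduces the *structure* of the acquisition protocol:
per subject, one random choreography containing each of the eight PGs
exactly once plus one FPG, repeated ten times; gesture durations uniform
in 600–1500 ms; dance filler of 1–3 times the neighboring propulsion
duration around every gesture; all 17 channels of the recording schema;
FSR channels high exactly over true-propulsion contact and silent during
FPGs and dance.

The signal model is deliberately simple: a propelling hand carries a
half-sine angular-velocity pulse (±150 deg/s peak) on its wheel-rotation
axis, signed by stroke direction, with a correlated biphasic acceleration;
rim contact adds broadband accelerometer vibration (σ = 1.5 m/s²) and
onset/release jolts — the physical cue that distinguishes a true
propulsion from an FPG, which replays the same template slightly
attenuated (×0.9) and without any contact signature. Dance filler is an
Ornstein–Uhlenbeck process (correlation time 0.25 s) with sporadic
sinusoidal arm-wave bursts; measurement noise is white Gaussian
(0.15 m/s², 3 deg/s at `noise_sd = 1`).

What it does **not** model: wheelchair dynamics and rolling resistance,
per-subject movement styles, soft-tissue artifacts, sensor bias and drift,
asynchronous sampling, or dance gestures that share low-frequency
structure with propulsion. Consequently, passing tests on synthetic data
demonstrate that the pipeline's machinery is correct and well-calibrated
under its stated assumptions — not that the published human-data
accuracies (which are dataset-dependent) would be reproduced on new
recordings.

## Known limitations

* **Boundary confusions inflate the event count.** At a bilateral
  gesture's edges the two side classifiers cross their detection
  thresholds 1–3 samples apart (each side sees independent noise in the
  decisive window), which fuses into a spurious one-sided gesture of
  33–100 ms flanking the true event. The 50 ms spike filter removes the
  one-sample confusions but keeps the ≥ 67 ms ones, leaving on the order
  of one extra event per replayed choreography on the standard synthetic
  corpus. Count exactness would require either per-side smoothing before
  fusion (not part of the standard pipeline) or a coarser filter than the
  50 ms specification.
* **FPG rejection weakens at short windows.** The contact signature that
  separates true from fake propulsions accumulates over the window; at
  `w = 10` (330 ms) rejection is intermittent, while at `w = 30` it is
  exact on the standard corpus.
* **Durations are underestimated** by the causal painter (see the latency
  section); the benchmark choreography shows the same signature (mean
  duration error 47.84% against FSR).

## Problem sizes used by the tests and the acceptance script

Unit tests run on corpora of 2×2 to 6×6 subjects×trials; the acceptance
properties and `scripts/acceptance.R` use the standard corpus of 8
subjects × 10 trials (~29,000 labeled windows per side before balancing,
~2,900 after), train the right classifier as a random forest and the left
as an RBF-kernel SVM over reduced grids at `w = 30, s = 5`, and replay one
trial per subject at `step = 1`. The exhaustive grids (14 SVM + 48 kNN +
72 random-forest combinations) are exercised on small synthetic datasets.
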