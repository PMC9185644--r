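# propulse

Online recognition, counting and timing of manual-wheelchair **propulsion
gestures** from wearable inertial sensors, for rehabilitation engineers
and wheelchair-dance teachers who need objective answers to three
questions about a choreography: *how many propulsions were performed, when
did each start, and how long did it last?*

## The method

A dancer wears one six-axis IMU (3-axis accelerometer + 3-axis gyroscope)
on the back of each hand, sampled at 30 Hz; a trunk sensor is optional
("three-sensor" vs "two-sensor" mode). The pipeline is:

* **Sliding windows.** A trial of *n* samples is segmented into
  *m* = ⌊(*n* − *w*)/*s*⌋ + 1 windows of size *w* advanced by step *s*
  (defaults *w* = 30, *s* = 5). For training, a window is labeled with a
  propulsion class when it contains the gesture, the gesture contains it,
  or their overlap is ≥ 0.7 *w* samples; otherwise it is *dance*. Labels
  come from palm force sensors (FSR) that log hand–rim contact during
  acquisition only.
* **Features.** Each of *N* input signals per side (8 in two-sensor mode,
  10 in three-sensor mode, including the per-sample norms |**a**| and
  |**ω**|) contributes *N*<sub>f</sub> = 19 features — 13 time-domain
  (mean, RMS, variance, SD, median, max, min, zero crossings, peaks,
  25th/75th percentile, kurtosis, skew) and 6 frequency-domain (peaks,
  mean, RMS, median, SD and spectral entropy of the periodogram after a
  causal 2nd-order 4 Hz low-pass Butterworth) — giving *N*·*N*<sub>f</sub>
  = 152 or 190 features per window.
* **Two side classifiers.** Per side, a 3-class model
  (*forward*, *backward*, *dance*) is trained with ANOVA-F feature
  selection (≤ 30 features) and grid-searched SVM / kNN / random-forest
  hyperparameters under seeded stratified 10-fold cross-validation, on a
  dataset whose dance class is undersampled to max(#forward, #backward).
* **Fusion.** A deterministic table maps the label pair to one of eight
  gestures — e.g. (F, D) → left-forward, (F, F) → forward, (F, B) →
  clockwise, (D, D) → dance (fake propulsions included). Fused gesture
  segments shorter than 50 ms are classifier confusions and are removed;
  each remaining non-dance segment is one **propulsion event** with an
  onset and duration, scored against FSR boundaries by signed onset error
  (MAE) and relative duration error |ref − pred|/ref.

Because the original human recordings are private, the package ships a
first-class synthetic generator (`simulate_corpus()`) that emulates the
acquisition protocol: per subject one random choreography of the eight
propulsion gestures plus one fake propulsion (600–1500 ms each) embedded
in dance filler, with FSR ground truth. See
`vignettes/propulsion-recognition.Rmd` for the signal model and its
limits.

## Worked example

Timing metrics on the bundled benchmark choreography (eight propulsion
events with FSR reference and online-classifier estimates):

```r
library(propulse)
bench <- reference_timing()
report <- score_timing(
  data.frame(onset_ms = bench$classifier_onset_ms,
             duration_ms = bench$classifier_duration_ms),
  data.frame(onset_ms = bench$fsr_onset_ms,
             duration_ms = bench$fsr_duration_ms))
report
#> <timing_report> 8/8 events matched to 8 references
#>   onset MAE 123.75 ms, mean duration error 47.84%
head(report$matched, 3)
#>   ref_onset_ms pred_onset_ms onset_error_ms ref_duration_ms pred_duration_ms duration_error_pct
#> 1         4740          4680            -60            1080              810           25.00000
#> 2         9600          9540            -60            1200              540           55.00000
#> 3        15030         15390            360            1260              450           64.28571
```

Onset errors are signed (negative = the classifier fired before rim
contact); their mean absolute value, 123.75 ms, is small against the ~1 s
propulsion timescale. Durations are systematically underestimated (mean
error 47.84%) — an inherent property of causal window painting, analyzed
in the vignette. The two tuned side classifiers (right: random forest,
0.9614; left: RBF SVM, 0.9391) combine to an overall two-sensor accuracy
of `overall_accuracy(0.9391, 0.9614)` = **90.29%** (printed elsewhere as
90.28, i.e. truncated).

End to end on synthetic data:

```r
corpus <- simulate_corpus(n_subjects = 2, trials_per_subject = 3, seed = 1)
grids <- list(svm = data.frame(kernel = "rbf", C = 10))
right <- train_side(corpus, "right", cfg = training_config(seed = 1),
                    algos = "svm", grids = grids)
right
#> <side_model> right classifier (two-sensor): svm [kernel=rbf, C=10]
#>   w=30 s=5, 30 features, CV accuracy 0.9904
left <- train_side(corpus, "left", cfg = training_config(seed = 1),
                   algos = "svm", grids = grids)
res <- recognize_trial(corpus[[4]]$recording, left, right, step = 1)
head(res$events, 3)
#>   gesture_id       gesture onset_ms duration_ms
#> 1          2 left-backward     2167         633
#> 2          6      backward    10367        1066
#> 3          1  left-forward    12467         766
score_timing(res$events, subset(corpus[[4]]$annotations, fsr_active))
#> <timing_report> 8/9 events matched to 8 references
#>   onset MAE 604.25 ms, mean duration error 21.09%
```

All eight true propulsions are recovered in order; the ninth event is a
134 ms boundary confusion, and the ~600 ms onset lag at *w* = 30 is the
detection-latency floor of the 70% labeling rule — both analyzed, with
the short-window timing configuration that removes the lag, in the
vignette.

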