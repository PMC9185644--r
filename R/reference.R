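# Published benchmark values bundled with the package: per-event onset and
# duration measurements of one instrumented wheelchair-dance choreography
# (eight propulsion gestures), with FSR contact boundaries as reference
# and the online classifier pipeline's estimates alongside, plus the two
# side classifiers' reported cross-validation accuracies in two-sensor
# mode. Used to validate the timing metrics and the bilateral accuracy
# aggregation.

#' Benchmark timing measurements of one choreography
#'
#' Eight propulsion events from an instrumented wheelchair-dance
#' choreography: FSR-measured onset and duration of each propulsion next
#' to the onset and duration estimated online by the classifier pipeline.
#' Rows are ordered by onset; `gesture_id` is the canonical 1-8 gesture
#' numbering (see [gesture_id()]).
#'
#' @return Data frame with columns `gesture_id`, `fsr_onset_ms`,
#'   `classifier_onset_ms`, `fsr_duration_ms`, `classifier_duration_ms`.
#' @seealso [score_timing()] to recompute the onset MAE (123.75 ms) and
#'   mean duration error (47.84%) from these rows.
#' @export
reference_timing <- function() {
  utils::read.csv(system.file("extdata", "choreography_timing_reference.csv",
                              package = "propulse", mustWork = TRUE))
}

#' Benchmark side-classifier accuracies (two-sensor mode)
#'
#' Reported 10-fold cross-validation accuracies of the tuned side
#' classifiers in two-sensor mode: right 0.9614 (random forest, window 30,
#' step 5), left 0.9391 (SVM, RBF kernel, C = 10). Their product is the
#' overall bilateral accuracy, 90.28%.
#'
#' @return Named numeric vector with elements `left` and `right`.
#' @export
reference_side_accuracies <- function() {
  c(left = 0.9391, right = 0.9614)
}
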