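# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# Small corpus: 2 subjects x 2 trials under the default study conditions.
tiny_corpus <- function() {
  if (is.null(.fixtures$corpus)) {
    .fixtures$corpus <- simulate_corpus(2, 2, seed = 7)
  }
  .fixtures$corpus
}

# Quick side models on the tiny corpus (single SVM configuration).
tiny_models <- function() {
  if (is.null(.fixtures$models)) {
    cfg <- training_config(n_folds = 5, seed = 1)
    grids <- list(svm = data.frame(kernel = "rbf", C = 10))
    .fixtures$models <- list(
      left = train_side(tiny_corpus(), "left", params = window_params(30, 5),
                        cfg = cfg, algos = "svm", grids = grids),
      right = train_side(tiny_corpus(), "right", params = window_params(30, 5),
                         cfg = cfg, algos = "svm", grids = grids))
  }
  .fixtures$models
}

# Minimal valid recording at an arbitrary rate; all channels zero unless
# overridden. fs = 1000 makes sample index == millisecond, convenient for
# window-labeling arithmetic.
make_rec <- function(n, fs = 1000, channels = list()) {
  df <- as.data.frame(matrix(0, n, 17))
  names(df) <- trial_channels()
  df$t_ms <- round(1000 * (0:(n - 1)) / fs)
  for (nm in names(channels)) df[[nm]] <- channels[[nm]]
  trial_recording(df, fs_hz = fs)
}

# Side-annotation table in the shape label_windows() expects.
side_ann <- function(label, onset_ms, duration_ms) {
  data.frame(label = label, onset_ms = onset_ms, duration_ms = duration_ms)
}

# A fused timeline data frame from segment triples.
make_timeline <- function(gesture, start_ms, end_ms) {
  structure(data.frame(gesture = gesture, gesture_id = gesture_id(gesture),
                       start_ms = start_ms, end_ms = end_ms),
            class = c("fused_timeline", "data.frame"))
}
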