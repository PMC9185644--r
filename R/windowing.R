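# Sliding-window segmentation and window labeling.
#
# A trial of n samples is cut into m = floor((n - w)/s) + 1 half-open
# windows of w samples advanced by s samples; window k (k = 0..m-1) covers
# samples [k*s, k*s + w). A window inherits a propulsion label when it
# fully contains the gesture, when the gesture fully contains it, or when
# their overlap is at least 70% of the window size; otherwise it is dance.

#' Sliding-window parameters
#'
#' @param w Window size in samples.
#' @param s Step in samples; must satisfy `1 <= s <= w`.
#' @return A `window_params` list.
#' @export
window_params <- function(w = 30L, s = 5L) {
  w <- as.integer(w); s <- as.integer(s)
  stopifnot(s >= 1L, s <= w)
  structure(list(w = w, s = s), class = "window_params")
}

#' Number of sliding windows in a trial
#'
#' `floor((n - w)/s) + 1` full windows fit in `n` samples; trailing samples
#' that cannot fill a whole window are dropped.
#'
#' @param n Number of samples in the trial.
#' @param params A [window_params()].
#' @return Integer window count.
#' @export
#' @examples
#' count_windows(300, window_params(30, 5)) # 55
count_windows <- function(n, params) {
  stopifnot(inherits(params, "window_params"))
  if (n < params$w) {
    stop("empty-trial error: trial has ", n, " samples, window needs ",
         params$w)
  }
  as.integer((n - params$w) %/% params$s) + 1L
}

#' Slide a window over a trial recording
#'
#' @param rec A `trial_recording`.
#' @param params A [window_params()].
#' @return Data frame of window boundaries: `k` (0-based index),
#'   `start_sample`, `end_sample` (1-based, half-open), `start_ms`,
#'   `end_ms` (half-open; the end of the final window is the next nominal
#'   timestamp when it falls beyond the trial).
#' @export
slide <- function(rec, params) {
  stopifnot(inherits(rec, "trial_recording"))
  n <- nrow(rec$data)
  m <- count_windows(n, params)
  k <- 0:(m - 1L)
  start <- k * params$s + 1L
  end <- start + params$w
  t_ms <- rec$data$t_ms
  step <- round(1000 / rec$fs_hz)
  end_ms <- ifelse(end <= n, t_ms[pmin(end, n)], t_ms[n] + step)
  data.frame(k = k, start_sample = start, end_sample = end,
             start_ms = t_ms[start], end_ms = end_ms)
}

# Per-side propulsion intervals for labeling: keep true propulsions
# (FSR-backed) in which this side's arm propels, tagged with the side's
# basic stroke. Fake propulsions and dance are excluded -> labeled dance.
side_annotations <- function(annotations, side = c("left", "right")) {
  side <- match.arg(side)
  validate_annotations(annotations)
  active <- if (!is.null(annotations$fsr_active)) annotations$fsr_active
            else rep(TRUE, nrow(annotations))
  if (side == "left" && !is.null(annotations$left_active)) {
    active <- active & annotations$left_active
  } else if (side == "right" && !is.null(annotations$right_active)) {
    active <- active & annotations$right_active
  }
  ann <- annotations[active, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(label = character(0), onset_ms = numeric(0),
                      duration_ms = numeric(0)))
  }
  data.frame(
    label = vapply(ann$label, side_basic_label, character(1), side = side),
    onset_ms = ann$onset_ms,
    duration_ms = ann$duration_ms,
    row.names = NULL
  )
}

#' Label sliding windows against propulsion intervals
#'
#' A window takes a propulsion label (`"forward"` or `"backward"`) when
#' (1) it fully contains the gesture interval, (2) the gesture fully
#' contains the window, or (3) at least 70% of the window's samples fall
#' inside the gesture (inclusive threshold). All other windows are dance.
#' Two qualifying gestures with different labels raise a labeling-conflict
#' error.
#'
#' @param rec The `trial_recording` the windows were cut from (provides the
#'   sample timestamps used to count overlap in samples).
#' @param windows Window data frame from [slide()].
#' @param annotations Side-relevant propulsion intervals: data frame with
#'   `label` in `{"forward","backward"}`, `onset_ms`, `duration_ms` (see
#'   [build_dataset()] for how these are derived from trial annotations).
#' @param min_overlap Fractional overlap threshold for case 3 (default
#'   0.7 of the window size, in samples).
#' @return Factor of labels (levels `forward`, `backward`, `dance`), one
#'   per window.
#' @export
label_windows <- function(rec, windows, annotations, min_overlap = 0.7) {
  stopifnot(inherits(rec, "trial_recording"))
  t_ms <- rec$data$t_ms
  w <- windows$end_sample[1] - windows$start_sample[1]
  labels <- rep("dance", nrow(windows))
  if (nrow(annotations) > 0) {
    bad <- setdiff(unique(annotations$label), c("forward", "backward"))
    if (length(bad) > 0) {
      stop("side annotations must be forward/backward, got: ",
           paste(bad, collapse = ", "))
    }
    g_on <- annotations$onset_ms
    g_off <- annotations$onset_ms + annotations$duration_ms
    for (i in seq_len(nrow(windows))) {
      ws <- windows$start_ms[i]
      we <- windows$end_ms[i]
      samp <- t_ms[windows$start_sample[i]:(windows$end_sample[i] - 1L)]
      hits <- character(0)
      for (j in seq_along(g_on)) {
        contains_gesture <- g_on[j] >= ws && g_off[j] <= we
        inside_gesture <- ws >= g_on[j] && we <= g_off[j]
        overlap <- sum(samp >= g_on[j] & samp < g_off[j])
        if (contains_gesture || inside_gesture ||
            overlap >= min_overlap * w - 1e-9) {
          hits <- c(hits, annotations$label[j])
        }
      }
      hits <- unique(hits)
      if (length(hits) > 1) {
        stop("labeling conflict: window ", windows$k[i],
             " qualifies for both ", paste(hits, collapse = " and "))
      }
      if (length(hits) == 1) labels[i] <- hits
    }
  }
  factor(labels, levels = basic_labels())
}

#' Label a single window
#'
#' Convenience wrapper over [label_windows()] for one window.
#'
#' @inheritParams label_windows
#' @param window One row of a [slide()] data frame.
#' @return A single label (`"forward"`, `"backward"` or `"dance"`).
#' @export
label_window <- function(rec, window, annotations, min_overlap = 0.7) {
  as.character(label_windows(rec, window[1, , drop = FALSE], annotations,
                             min_overlap))
}

# Seeded undersampling of the dance class down to max(#forward, #backward).
balance_classes <- function(y, seed) {
  counts <- table(factor(y, levels = basic_labels()))
  if (any(counts == 0)) {
    stop("degenerate-dataset error: class(es) with zero windows: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  target <- max(counts["forward"], counts["backward"])
  keep <- which(y != "dance")
  dance_idx <- which(y == "dance")
  if (length(dance_idx) > target) {
    withr::local_seed(as.integer(seed))
    dance_idx <- sort(sample(dance_idx, target))
  }
  sort(c(keep, dance_idx))
}

#' Assemble a balanced labeled window dataset from trials
#'
#' Pools labeled windows over all trials for one classifier side, computes
#' the feature matrix, and randomly undersamples the dance class down to
#' `max(#forward, #backward)` (seeded).
#'
#' @param trials List of trials, each a list with `recording` and
#'   `annotations` (as produced by [simulate_corpus()] / [read_corpus()]).
#' @param side `"left"` or `"right"`.
#' @param mode `"two-sensor"` (hand only) or `"three-sensor"` (hand +
#'   trunk).
#' @param params A [window_params()].
#' @param filt A [filter_spec()] for the frequency-domain features.
#' @param seed Seed for the dance undersampling.
#' @param balance Undersample dance (default `TRUE`).
#' @return A `labeled_dataset`: list with feature matrix `X` (one row per
#'   kept window, named columns), factor `y`, integer `groups` (trial index
#'   of each window, for trial-held-out validation), `counts` (class counts
#'   before and after balancing), plus the side/mode/params/seed metadata.
#' @export
build_dataset <- function(trials, side = c("left", "right"),
                          mode = c("two-sensor", "three-sensor"),
                          params = window_params(), filt = filter_spec(),
                          seed = 1L, balance = TRUE) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (length(trials) < 1) stop("at least one trial is required")
  xs <- vector("list", length(trials))
  ys <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    feats <- extract_features(tr$recording, side = side, mode = mode,
                              params = params, filt = filt)
    ann <- side_annotations(tr$annotations, side)
    xs[[i]] <- feats$features
    ys[[i]] <- label_windows(tr$recording, feats$windows, ann)
  }
  X <- do.call(rbind, xs)
  y <- factor(unlist(lapply(ys, as.character)), levels = basic_labels())
  groups <- rep(seq_along(trials), vapply(xs, nrow, integer(1)))
  raw_counts <- table(y)
  idx <- if (balance) balance_classes(y, seed) else seq_along(y)
  structure(list(X = X[idx, , drop = FALSE], y = y[idx],
                 groups = groups[idx],
                 counts = list(raw = raw_counts, kept = table(y[idx])),
                 side = side, mode = mode, params = params, seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  k <- x$counts$kept
  cat(sprintf(
    "<labeled_dataset> %s/%s: %d windows (fwd %d, bwd %d, dance %d), %d features\n",
    x$side, x$mode, nrow(x$X), k["forward"], k["backward"], k["dance"],
    ncol(x$X)))
  invisible(x)
}
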