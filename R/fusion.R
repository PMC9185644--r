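# Bilateral fusion and event quantification. The two side classifiers each
# emit one of {forward, backward, dance} per window; a deterministic 3x3
# lookup rebuilds the eight specific propulsion gestures, a minimum-
# duration filter removes sub-50 ms confusions, and the surviving segments
# become counted, timed propulsion events.

#' Fuse one pair of side-classifier labels
#'
#' The deterministic bilateral lookup: (left, right) = (F, D) is a
#' left-forward push, (F, F) a forward push, (F, B) a clockwise turn,
#' (B, F) an anticlockwise turn, and so on; (D, D) is dance (which
#' includes fake propulsions).
#'
#' @param left,right Labels in `{"forward", "backward", "dance"}`.
#' @return The fused gesture label (one of the eight propulsion gestures
#'   or `"dance"`).
#' @export
#' @examples
#' fuse("forward", "backward") # clockwise
fuse <- function(left, right) {
  ok <- c(left, right) %in% basic_labels()
  if (!all(ok)) {
    stop("unknown side label(s): ",
         paste(unique(c(left, right)[!ok]), collapse = ", "))
  }
  fusion_table()[paste(left, right, sep = "|")]
}

fusion_table <- function() {
  c("forward|dance"    = "left-forward",
    "backward|dance"   = "left-backward",
    "dance|forward"    = "right-forward",
    "dance|backward"   = "right-backward",
    "forward|forward"  = "forward",
    "backward|backward" = "backward",
    "forward|backward" = "clockwise",
    "backward|forward" = "anticlockwise",
    "dance|dance"      = "dance")
}

#' Replay a recording through a side classifier
#'
#' Classifies every sliding window with the side model and paints each
#' window's label onto its step span -- the window's newest `s` samples --
#' yielding a causal, contiguous, gap-free prediction stream starting at
#' the end of the first window's look-back.
#'
#' @param rec A `trial_recording`.
#' @param model A `side_model` from [train_side()].
#' @param paint `"step"` (default; the label covers the window's newest
#'   `step` samples) or `"full-window"` (the label covers the whole
#'   window; overlapping paints are resolved by the newest window, which
#'   makes the stream non-causal but removes most of the onset detection
#'   latency).
#' @param step Inference stride in samples: how often the online system
#'   re-classifies its look-back buffer. Defaults to the model's training
#'   step `s`. `step = 1` replays the truly online regime -- one decision
#'   per new sample -- which is what gives the 50 ms spike filter
#'   sub-step-size confusions to remove.
#' @return A `prediction_stream` data frame: `k`, `label`, `start_ms`,
#'   `end_ms` (half-open, contiguous, ordered spans).
#' @export
predict_stream <- function(rec, model, paint = c("step", "full-window"),
                           step = NULL) {
  stopifnot(inherits(rec, "trial_recording"), inherits(model, "side_model"))
  paint <- match.arg(paint)
  if (is.null(step)) step <- model$window_params$s
  step <- as.integer(step)
  stopifnot(step >= 1, step <= model$window_params$w)
  feats <- extract_features(rec, side = model$side, mode = model$mode,
                            params = window_params(model$window_params$w,
                                                   step),
                            filt = model$filter)
  missing_feats <- setdiff(model$selected_features, colnames(feats$features))
  if (length(missing_feats) > 0) {
    stop("model/recording schema mismatch: missing feature(s) ",
         paste(utils::head(missing_feats, 3), collapse = ", "))
  }
  labels <- predict_side(model, feats$features)
  wins <- feats$windows
  s <- step
  t_ms <- rec$data$t_ms
  n <- length(t_ms)
  step <- round(1000 / rec$fs_hz)
  if (paint == "step") {
    start_idx <- wins$end_sample - s
    out <- data.frame(k = wins$k, label = labels,
                      start_ms = t_ms[start_idx],
                      end_ms = wins$end_ms)
  } else {
    # every window paints its whole span; newer windows overwrite older
    # ones, so a sample's label comes from the newest window covering it.
    # For the step span ending window i that is window min(m, i + (w-s)%/%s).
    start_idx <- wins$end_sample - s
    lab <- as.character(labels)
    m <- nrow(wins)
    w <- model$window_params$w
    ahead <- (w - s) %/% s
    painted <- lab[pmin(m, seq_len(m) + ahead)]
    # the first window also paints its look-back [0, w - s)
    pre <- data.frame(k = -1L, label = lab[pmin(m, 1L + ahead)],
                      start_ms = t_ms[1],
                      end_ms = t_ms[wins$end_sample[1] - s])
    out <- rbind(pre, data.frame(k = wins$k, label = painted,
                                 start_ms = t_ms[start_idx],
                                 end_ms = wins$end_ms))
    out$label <- factor(out$label, levels = basic_labels())
  }
  structure(out, class = c("prediction_stream", "data.frame"),
            side = model$side)
}

#' Fuse two prediction streams into a gesture timeline
#'
#' Requires both streams to share the same window grid (same window size,
#' step and trial). Each aligned span pair is fused with [fuse()] and
#' runs of equal gestures are merged into segments.
#'
#' @param left,right `prediction_stream`s from the left and right side
#'   models.
#' @return A `fused_timeline` data frame: `gesture`, `gesture_id`,
#'   `start_ms`, `end_ms`; segments tile the replayed span and adjacent
#'   segments carry different gestures.
#' @export
fuse_streams <- function(left, right) {
  if (nrow(left) != nrow(right) ||
      any(left$start_ms != right$start_ms) ||
      any(left$end_ms != right$end_ms)) {
    stop("prediction streams are not aligned (different window grid?)")
  }
  fused <- unname(fuse_vec(as.character(left$label),
                           as.character(right$label)))
  collapse_segments(fused, left$start_ms, left$end_ms)
}

fuse_vec <- function(left, right) {
  fusion_table()[paste(left, right, sep = "|")]
}

collapse_segments <- function(gesture, start_ms, end_ms) {
  r <- rle(gesture)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(gesture = r$values,
                    gesture_id = gesture_id(r$values),
                    start_ms = start_ms[starts],
                    end_ms = end_ms[ends])
  structure(out, class = c("fused_timeline", "data.frame"))
}

#' Remove short gesture spikes from a fused timeline
#'
#' Non-dance segments shorter than `min_ms` are classifier confusions:
#' they are relabeled dance and adjacent equal segments merged. The
#' operation is idempotent and never increases the number of non-dance
#' segments.
#'
#' @param timeline A `fused_timeline` from [fuse_streams()].
#' @param min_ms Minimum duration of a real gesture in ms (default 50).
#' @return A despiked `fused_timeline`.
#' @export
despike <- function(timeline, min_ms = 50) {
  g <- as.character(timeline$gesture)
  dur <- timeline$end_ms - timeline$start_ms
  g[g != "dance" & dur < min_ms] <- "dance"
  collapse_segments(g, timeline$start_ms, timeline$end_ms)
}

#' Extract propulsion events from a despiked timeline
#'
#' One event per maximal non-dance segment: onset is the segment start,
#' duration its length.
#'
#' @param timeline A (despiked) `fused_timeline`.
#' @return Data frame of `propulsion_event`s: `gesture_id` (1-8),
#'   `gesture`, `onset_ms`, `duration_ms`, ordered by onset.
#' @export
extract_events <- function(timeline) {
  seg <- timeline[timeline$gesture != "dance", , drop = FALSE]
  data.frame(gesture_id = seg$gesture_id,
             gesture = as.character(seg$gesture),
             onset_ms = seg$start_ms,
             duration_ms = seg$end_ms - seg$start_ms,
             row.names = NULL)
}

#' Recognize propulsion events in a trial
#'
#' End-to-end online replay: classify every window with both side models,
#' fuse, despike, and extract events.
#'
#' @param rec A `trial_recording`.
#' @param left_model,right_model Trained `side_model`s.
#' @param min_ms Spike-filter threshold in ms (default 50).
#' @param paint,step Prediction-to-time assignment and inference stride,
#'   see [predict_stream()].
#' @return List with `events` (see [extract_events()]) and `timeline` (the
#'   despiked `fused_timeline`).
#' @export
recognize_trial <- function(rec, left_model, right_model, min_ms = 50,
                            paint = "step", step = NULL) {
  stopifnot(left_model$side == "left", right_model$side == "right")
  tl <- fuse_streams(predict_stream(rec, left_model, paint, step),
                     predict_stream(rec, right_model, paint, step))
  tl <- despike(tl, min_ms)
  list(events = extract_events(tl), timeline = tl)
}

#' Score predicted event timing against reference boundaries
#'
#' Events are matched to reference annotations greedily by nearest onset
#' (within `max_match_ms`); matched pairs yield signed onset errors
#' (predicted minus reference; negative = early), their mean absolute
#' error, and relative duration errors `|ref - pred| / ref * 100` with
#' their mean. Unmatched events/references are reported separately.
#'
#' @param events Event data frame with `onset_ms` and `duration_ms` (from
#'   [extract_events()], or any table in that shape).
#' @param reference Reference data frame with `onset_ms` and `duration_ms`
#'   (e.g. propulsion annotations, or [fsr_boundaries()] intervals
#'   augmented with durations). Must be non-empty.
#' @param max_match_ms Maximum onset distance for a match (default 1000).
#' @return A `timing_report`: list with `matched` (per-event table),
#'   `mae_ms`, `mean_duration_error_pct`, `n_events`, `n_reference`,
#'   `n_unmatched_events`, `n_unmatched_reference`.
#' @export
score_timing <- function(events, reference, max_match_ms = 1000) {
  if (is.null(reference) || nrow(reference) == 0) {
    stop("empty reference: nothing to score against")
  }
  ne <- nrow(events)
  nr <- nrow(reference)
  matched_e <- rep(FALSE, ne)
  matched_r <- rep(FALSE, nr)
  pairs <- list()
  if (ne > 0) {
    d <- abs(outer(events$onset_ms, reference$onset_ms, "-"))
    repeat {
      d_open <- d
      d_open[matched_e, ] <- Inf
      d_open[, matched_r] <- Inf
      if (all(!is.finite(d_open)) || min(d_open) > max_match_ms) break
      ij <- which(d_open == min(d_open), arr.ind = TRUE)[1, ]
      matched_e[ij[1]] <- TRUE
      matched_r[ij[2]] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(ij[1], ij[2])
    }
  }
  if (length(pairs) > 0) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(reference$onset_ms[pm[, 2]]), , drop = FALSE]
    matched <- data.frame(
      ref_onset_ms = reference$onset_ms[pm[, 2]],
      pred_onset_ms = events$onset_ms[pm[, 1]],
      onset_error_ms = events$onset_ms[pm[, 1]] -
        reference$onset_ms[pm[, 2]],
      ref_duration_ms = reference$duration_ms[pm[, 2]],
      pred_duration_ms = events$duration_ms[pm[, 1]])
    matched$duration_error_pct <-
      abs(matched$ref_duration_ms - matched$pred_duration_ms) /
      matched$ref_duration_ms * 100
    mae <- mean(abs(matched$onset_error_ms))
    mde <- mean(matched$duration_error_pct)
  } else {
    matched <- data.frame(ref_onset_ms = numeric(0),
                          pred_onset_ms = numeric(0),
                          onset_error_ms = numeric(0),
                          ref_duration_ms = numeric(0),
                          pred_duration_ms = numeric(0),
                          duration_error_pct = numeric(0))
    mae <- NA_real_
    mde <- NA_real_
  }
  structure(list(matched = matched, mae_ms = mae,
                 mean_duration_error_pct = mde,
                 n_events = ne, n_reference = nr,
                 n_unmatched_events = sum(!matched_e),
                 n_unmatched_reference = sum(!matched_r)),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf(
    "<timing_report> %d/%d events matched to %d references\n  onset MAE %.2f ms, mean duration error %.2f%%\n",
    x$n_events - x$n_unmatched_events, x$n_events, x$n_reference,
    x$mae_ms, x$mean_duration_error_pct))
  invisible(x)
}

#' Overall bilateral accuracy
#'
#' The recognizer's overall accuracy is reported as the product of the two
#' side classifiers' accuracies, which assumes their errors are
#' independent; windows where both sides err in a compensating way make
#' this a conservative approximation.
#'
#' @param left_accuracy,right_accuracy Side accuracies as fractions in
#'   `[0, 1]`.
#' @return Overall accuracy fraction.
#' @export
#' @examples
#' overall_accuracy(0.9391, 0.9614) * 100 # ~90.28
overall_accuracy <- function(left_accuracy, right_accuracy) {
  stopifnot(left_accuracy >= 0, left_accuracy <= 1,
            right_accuracy >= 0, right_accuracy <= 1)
  left_accuracy * right_accuracy
}
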