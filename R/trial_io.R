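# Trial recordings: 17 named channels sampled nominally at 30 Hz, stored as
# one comma-separated file per trial with a single header line and a fixed
# column order. Accelerations are in m/s^2 (gravity offset +9.81 on the
# vertical axes), angular rates in deg/s, timestamps in integer
# milliseconds from trial start, force-sensor (FSR) channels dimensionless
# (binary 0/1 unless analog emulation is enabled in the simulator).

#' Channel schema of a trial recording
#'
#' The 17 recorded variables in their fixed file order: trunk accelerometer
#' Z, trunk gyroscope, left-hand accelerometer X/Y/Z, left-hand gyroscope
#' X/Y/Z, right-hand accelerometer X/Y/Z, right-hand gyroscope X/Y/Z,
#' sampling time (ms), left and right hand force sensors. The trunk
#' gyroscope is stored as a single channel named `trunk_gyro`; which
#' physical axis it carries is a mounting convention, not a property of the
#' file format (see `vignette("propulsion-recognition")`).
#'
#' @return Character vector of the 17 column names.
#' @export
#' @examples
#' trial_channels()
trial_channels <- function() {
  c("trunk_acc_z", "trunk_gyro",
    "l_acc_x", "l_acc_y", "l_acc_z", "l_gyro_x", "l_gyro_y", "l_gyro_z",
    "r_acc_x", "r_acc_y", "r_acc_z", "r_gyro_x", "r_gyro_y", "r_gyro_z",
    "t_ms", "l_fsr", "r_fsr")
}

#' Construct a trial recording
#'
#' Wraps a data frame with the 17-channel schema (see [trial_channels()])
#' into a validated `trial_recording` object. Timestamps must be strictly
#' increasing; the nominal sampling rate is inferred from the timestamps
#' when not supplied.
#'
#' @param data Data frame with exactly the 17 schema columns.
#' @param fs_hz Nominal sampling rate in Hz; inferred from `t_ms` if `NULL`.
#' @return A `trial_recording` object (list with `data` and `fs_hz`).
#' @export
trial_recording <- function(data, fs_hz = NULL) {
  chans <- trial_channels()
  missing_cols <- setdiff(chans, names(data))
  extra_cols <- setdiff(names(data), chans)
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    stop("trial schema error: ",
         if (length(missing_cols) > 0)
           paste0("missing column(s) ", paste(missing_cols, collapse = ", ")),
         if (length(missing_cols) > 0 && length(extra_cols) > 0) "; ",
         if (length(extra_cols) > 0)
           paste0("unexpected column(s) ", paste(extra_cols, collapse = ", ")))
  }
  data <- data[, chans]
  for (nm in chans) data[[nm]] <- as.double(data[[nm]])
  if (nrow(data) < 2) stop("trial must contain at least 2 samples")
  if (any(!is.finite(data$t_ms)) || any(diff(data$t_ms) <= 0)) {
    stop("trial validation error: timestamps must be finite and strictly increasing")
  }
  if (is.null(fs_hz)) fs_hz <- infer_fs(data$t_ms)
  structure(list(data = data, fs_hz = fs_hz), class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %d samples, %.4g Hz, %.1f s\n",
              nrow(x$data), x$fs_hz,
              (x$data$t_ms[nrow(x$data)] - x$data$t_ms[1]) / 1000))
  invisible(x)
}

# Nominal rate from timestamps. Integer-ms timestamps at 30 Hz alternate
# 33/34 ms steps, so the single-lag median is biased (1000/33 = 30.3 Hz);
# the median of lag-L differences divided by L is exact for any uniform
# grid with rounding error < L/2 ms.
infer_fs <- function(t_ms) {
  n <- length(t_ms)
  lag <- min(30L, n - 1L)
  steps <- (t_ms[(lag + 1L):n] - t_ms[1L:(n - lag)]) / lag
  1000 / stats::median(steps)
}

#' Write a trial recording to a CSV file
#'
#' One header line naming all 17 channels, fixed column order, comma
#' separated. Round-trips bit-exactly through [read_trial()] for integer
#' timestamps and full-precision channel values.
#'
#' @param rec A `trial_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  out <- rec$data
  for (nm in names(out)) {
    # %.17g round-trips doubles exactly; write.csv alone truncates
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial recording from a CSV file
#'
#' Validates the 17-column schema and strictly increasing timestamps, and
#' infers the nominal sampling rate from the timestamp grid.
#'
#' @param path Path to a trial CSV written by [write_trial()] (or any file
#'   in the same dialect).
#' @return A `trial_recording`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  trial_recording(df)
}

#' Write gesture annotations to a JSON sidecar
#'
#' @param annotations Annotation data frame (columns `label`, `onset_ms`,
#'   `duration_ms`, `fsr_active`, `left_active`, `right_active`, `source`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read gesture annotations from a JSON sidecar
#'
#' @param path Path to a JSON file written by [write_annotations()].
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- jsonlite::fromJSON(path)
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  need <- c("label", "onset_ms", "duration_ms")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(ann$duration_ms <= 0)) stop("annotation durations must be positive")
  if (any(ann$onset_ms < 0)) stop("annotation onsets must be non-negative")
  invisible(ann)
}

#' Hand-rim contact intervals from a force-sensor channel
#'
#' Maximal runs of samples where the FSR channel exceeds `threshold`,
#' reported as half-open `[onset_ms, offset_ms)` intervals. The offset of a
#' run ending at sample `i` is the timestamp of sample `i + 1` (or the last
#' timestamp plus one nominal step when the run reaches the end of the
#' trial).
#'
#' @param rec A `trial_recording`.
#' @param side `"left"` or `"right"`.
#' @param threshold Contact threshold (default 0.5, suited to the binary
#'   0/1 FSR channels written by the simulator). Must be >= 0.
#' @return Data frame with columns `onset_ms`, `offset_ms` (zero rows when
#'   no contact is detected). Intervals are disjoint and sorted.
#' @export
fsr_boundaries <- function(rec, side = c("left", "right"), threshold = 0.5) {
  stopifnot(inherits(rec, "trial_recording"), threshold >= 0)
  side <- match.arg(side)
  fsr <- rec$data[[if (side == "left") "l_fsr" else "r_fsr"]]
  t_ms <- rec$data$t_ms
  high <- fsr > threshold
  if (!any(high)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  i0 <- starts[keep]
  i1 <- ends[keep]
  step <- round(1000 / rec$fs_hz)
  offset <- ifelse(i1 < length(t_ms), t_ms[pmin(i1 + 1L, length(t_ms))],
                   t_ms[length(t_ms)] + step)
  data.frame(onset_ms = t_ms[i0], offset_ms = offset)
}
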