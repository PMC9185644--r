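# Per-window signal selection and the 19 statistical features.
#
# Each side classifier sees 8 signals in two-sensor mode (the hand's three
# accelerometer axes, three gyroscope axes, and the per-sample Euclidean
# norms |a| and |omega|) or 10 in three-sensor mode (plus trunk
# accelerometer Z and the trunk gyroscope). Every signal contributes 13
# time-domain features computed on the raw window and 6 frequency-domain
# features computed on a causally low-pass-filtered copy, for 19 per
# signal: 152 features in two-sensor mode, 190 in three-sensor mode.

#' Low-pass filter specification for the frequency-domain features
#'
#' Second-order Butterworth low-pass, 4 Hz cutoff at a 30 Hz sampling
#' rate by default. Applied causally (forward only, zero initial state per
#' window): an online system cannot see future samples.
#'
#' @param order Filter order (default 2).
#' @param cutoff_hz Cutoff frequency in Hz (default 4); must be below the
#'   Nyquist frequency.
#' @param fs_hz Sampling rate in Hz (default 30).
#' @return A `filter_spec` with the Butterworth coefficients attached.
#' @export
filter_spec <- function(order = 2, cutoff_hz = 4, fs_hz = 30) {
  stopifnot(cutoff_hz < fs_hz / 2, order >= 1)
  bt <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  structure(list(order = order, cutoff_hz = cutoff_hz, fs_hz = fs_hz,
                 b = as.numeric(bt$b), a = as.numeric(bt$a)),
            class = "filter_spec")
}

# Causal IIR filtering of each column of a matrix, zero initial state.
# Direct-form I: the moving-average part via one-sided convolution with
# zero-padded history, then the autoregressive part recursively.
filter_columns <- function(X, filt) {
  X <- as.matrix(X)
  nb <- length(filt$b)
  pad <- matrix(0, nb - 1L, ncol(X))
  ma <- stats::filter(rbind(pad, X), filt$b, method = "convolution",
                      sides = 1)
  ma <- ma[-seq_len(nb - 1L), , drop = FALSE]
  out <- stats::filter(ma, -filt$a[-1], method = "recursive")
  matrix(as.numeric(out), nrow(X), ncol(X), dimnames = dimnames(X))
}

# Signal names are side-neutral so that left and right models share one
# feature-naming scheme.
signal_names <- function(mode) {
  hand <- c("hand_acc_x", "hand_acc_y", "hand_acc_z",
            "hand_gyro_x", "hand_gyro_y", "hand_gyro_z",
            "hand_acc_norm", "hand_gyro_norm")
  if (mode == "three-sensor") c("trunk_acc_z", "trunk_gyro", hand) else hand
}

time_feature_names <- function() {
  c("mean", "rms", "variance", "sd", "median", "max", "min",
    "zero_crossings", "n_peaks", "p25", "p75", "kurtosis", "skew")
}

freq_feature_names <- function() {
  c("psd_n_peaks", "psd_mean", "psd_rms", "psd_median", "psd_sd",
    "psd_entropy")
}

#' Feature names for a sensor mode
#'
#' @param mode `"two-sensor"` or `"three-sensor"`.
#' @return Character vector of `signal__feature` names (length 152 or 190).
#' @export
feature_names <- function(mode = c("two-sensor", "three-sensor")) {
  mode <- match.arg(mode)
  as.vector(t(outer(signal_names(mode),
                    c(time_feature_names(), freq_feature_names()),
                    paste, sep = "__")))
}

#' Select a window's input signals for one classifier
#'
#' Two-sensor mode: the side's hand accelerometer X/Y/Z, gyroscope X/Y/Z,
#' and the per-sample Euclidean norms of the two triads (8 signals).
#' Three-sensor mode prepends trunk accelerometer Z and the trunk
#' gyroscope (10 signals).
#'
#' @param rec A `trial_recording`.
#' @param side `"left"` or `"right"`.
#' @param mode `"two-sensor"` or `"three-sensor"`.
#' @param window Optional one-row window data frame from [slide()]; when
#'   supplied, only that window's samples are returned.
#' @return Numeric matrix, one column per signal, with side-neutral column
#'   names.
#' @export
select_signals <- function(rec, side = c("left", "right"),
                           mode = c("two-sensor", "three-sensor"),
                           window = NULL) {
  stopifnot(inherits(rec, "trial_recording"))
  side <- match.arg(side)
  mode <- match.arg(mode)
  pre <- if (side == "left") "l_" else "r_"
  d <- rec$data
  acc <- as.matrix(d[, paste0(pre, c("acc_x", "acc_y", "acc_z"))])
  gyr <- as.matrix(d[, paste0(pre, c("gyro_x", "gyro_y", "gyro_z"))])
  out <- cbind(acc, gyr,
               sqrt(rowSums(acc^2)), sqrt(rowSums(gyr^2)))
  if (mode == "three-sensor") {
    out <- cbind(d$trunk_acc_z, d$trunk_gyro, out)
  }
  colnames(out) <- signal_names(mode)
  if (!is.null(window)) {
    out <- out[window$start_sample[1]:(window$end_sample[1] - 1L), ,
               drop = FALSE]
  }
  out
}

#' Time-domain features of a signal window
#'
#' Mean, RMS, sample variance, standard deviation, median, maximum,
#' minimum, zero-crossing count, peak count, 25th and 75th percentiles
#' (linear interpolation), excess kurtosis, and skewness. Zero crossings
#' are strict sign changes of the mean-centered series (raw accelerometer
#' channels carry the gravity offset and would otherwise never cross
#' zero); peaks are strict local maxima (`x[i-1] < x[i] > x[i+1]`).
#' Kurtosis and skewness use population moments (`m4/m2^2 - 3`,
#' `m3/m2^(3/2)`) and are defined as 0 for zero-variance input.
#'
#' @param x Numeric vector of length >= 2.
#' @return Named numeric vector of 13 features.
#' @export
#' @examples
#' time_features(c(0, 1, 0, 2, 0))[["n_peaks"]] # 2
time_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  mu <- mean(x)
  xs <- sort(x)
  m2 <- mean((x - mu)^2)
  v <- m2 * n / (n - 1)
  xc <- x - mu
  sgn <- sign(xc)
  sgn <- sgn[sgn != 0]
  zc <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0
  peaks <- count_peaks(x)
  if (m2 > 0) {
    kurt <- mean(xc^4) / m2^2 - 3
    skew <- mean(xc^3) / m2^1.5
  } else {
    kurt <- 0
    skew <- 0
  }
  c(mean = mu,
    rms = sqrt(mean(x^2)),
    variance = v,
    sd = sqrt(v),
    median = stats::median(x),
    max = xs[n],
    min = xs[1],
    zero_crossings = zc,
    n_peaks = peaks,
    p25 = unname(stats::quantile(x, 0.25)),
    p75 = unname(stats::quantile(x, 0.75)),
    kurtosis = kurt,
    skew = skew)
}

count_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(0L)
  sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n])
}

# One-sided periodogram of a mean-removed series: P_j = |X_j|^2 / n for
# the positive-frequency bins j = 1..floor(n/2) (DC excluded). No Welch
# averaging: windows are at most a few dozen samples.
periodogram <- function(x) {
  n <- length(x)
  xf <- stats::fft(x - mean(x))
  (Mod(xf)^2 / n)[2:(n %/% 2 + 1L)]
}

psd_entropy <- function(p) {
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log(p))
}

#' Frequency-domain features of a signal window
#'
#' The window is filtered causally with the Butterworth specification,
#' mean-removed, and its one-sided periodogram (DC excluded) computed.
#' Returns the PSD peak count (strict local maxima), mean, RMS, median,
#' standard deviation, and spectral entropy `-sum(p log p)` of the PSD
#' normalized to unit mass (0 for an all-zero series).
#'
#' @param x Numeric vector of length >= 8.
#' @param filt A [filter_spec()].
#' @return Named numeric vector of 6 features.
#' @export
freq_features <- function(x, filt = filter_spec()) {
  stopifnot(length(x) >= 8, inherits(filt, "filter_spec"))
  xf <- filter_columns(matrix(x, ncol = 1), filt)[, 1]
  p <- periodogram(xf)
  c(psd_n_peaks = count_peaks(p),
    psd_mean = mean(p),
    psd_rms = sqrt(mean(p^2)),
    psd_median = stats::median(p),
    psd_sd = stats::sd(p),
    psd_entropy = psd_entropy(p))
}

#' Feature vector of one window
#'
#' Concatenates the 13 time-domain features (raw signals) and 6
#' frequency-domain features (filtered signals) over all input signals in
#' the fixed [feature_names()] order: 152 values in two-sensor mode, 190
#' in three-sensor mode.
#'
#' @param signals Signal matrix from [select_signals()] (one column per
#'   signal, `w` rows).
#' @param filt A [filter_spec()].
#' @return Named numeric vector of length `ncol(signals) * 19`.
#' @export
featurize <- function(signals, filt = filter_spec()) {
  signals <- as.matrix(signals)
  w <- nrow(signals)
  stopifnot(w >= 8)
  filtered <- filter_columns(signals, filt)
  out <- lapply(seq_len(ncol(signals)), function(j) {
    c(time_features(signals[, j]), freq_block(filtered[, j]))
  })
  res <- unlist(out)
  names(res) <- as.vector(t(outer(colnames(signals),
                                  c(time_feature_names(),
                                    freq_feature_names()),
                                  paste, sep = "__")))
  res
}

#' Feature matrix for every sliding window of a trial
#'
#' Vectorized equivalent of calling [featurize()] on each window of
#' [slide()].
#'
#' @param rec A `trial_recording`.
#' @param side `"left"` or `"right"`.
#' @param mode `"two-sensor"` or `"three-sensor"`.
#' @param params A [window_params()].
#' @param filt A [filter_spec()].
#' @return List with `features` (matrix, one row per window, named
#'   columns) and `windows` (the [slide()] data frame).
#' @export
extract_features <- function(rec, side = c("left", "right"),
                             mode = c("two-sensor", "three-sensor"),
                             params = window_params(),
                             filt = filter_spec()) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  sig <- select_signals(rec, side, mode)
  wins <- slide(rec, params)
  m <- nrow(wins)
  w <- params$w
  idx <- outer(seq_len(w) - 1L, wins$start_sample, "+")
  nfeat <- 19L
  X <- matrix(NA_real_, m, ncol(sig) * nfeat)
  for (j in seq_len(ncol(sig))) {
    W <- matrix(sig[idx, j], w, m)           # one column per window
    Wf <- filter_columns(W, filt)
    cols <- (j - 1L) * nfeat + seq_len(nfeat)
    X[, cols] <- t(rbind(apply(W, 2, time_features),
                         apply(Wf, 2, freq_block)))
  }
  colnames(X) <- feature_names(mode)
  list(features = X, windows = wins)
}

freq_block <- function(xf) {
  p <- periodogram(xf)
  c(count_peaks(p), mean(p), sqrt(mean(p^2)), stats::median(p),
    stats::sd(p), psd_entropy(p))
}
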