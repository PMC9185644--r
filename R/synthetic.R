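# Synthetic wheelchair-dance choreography generator.
#
# Emulates the instrumented trials used to train the recognizer: each
# choreography contains the eight specific propulsion gestures (PGs) plus
# one fake propulsion gesture (FPG) in random order, separated by freely
# improvised dance filler. Propulsion-like gestures last 600-1500 ms; the
# dance gap around a propulsion lasts 1-3 times its duration. During a
# true PG the palm force sensor (FSR) of every propelling hand is high;
# during FPGs and dance it is exactly zero.
#
# Signal model (the recordings are synthetic; no claim of biomechanical
# fidelity): a propelling hand carries a half-sine angular-velocity pulse
# on its wheel-rotation gyro axis, signed by stroke direction, with a
# correlated biphasic acceleration pulse. Rim contact adds a broadband
# contact vibration on the accelerometer plus onset/offset jolts -- the
# physical cue that lets a classifier separate true propulsions from FPGs,
# which replay the same kinematic template slightly attenuated and without
# any contact signature. Dance filler is a smoothed (Ornstein-Uhlenbeck)
# noise process with occasional sinusoidal arm-wave bursts: nonstationary
# but propulsion-free.

#' Simulator configuration
#'
#' Parameters of the synthetic trial generator. Defaults define the
#' standard study conditions used throughout the package tests.
#'
#' @param fs_hz Sampling rate in Hz (default 30).
#' @param noise_sd Master measurement-noise scale: every channel receives
#'   additive Gaussian noise with standard deviation `noise_sd` times a
#'   per-channel base (0.15 m/s^2 accelerometer, 3 deg/s gyroscope).
#'   `noise_sd = 0` makes synthesis deterministic given the seed.
#' @param dance_gap_range Multiplier range for dance filler: the gap before
#'   a propulsion is uniform in `dance_gap_range` times that propulsion's
#'   duration.
#' @param seed Integer seed for trial synthesis.
#' @param duration_range_ms Range of propulsion-like gesture durations.
#' @param propulsion_gyro_amp Peak angular velocity of the propulsion pulse
#'   (deg/s).
#' @param propulsion_acc_amp Peak acceleration of the propulsion pulse
#'   (m/s^2).
#' @param fpg_scale Amplitude attenuation of fake propulsions relative to
#'   true ones (free arm swing without wheel load).
#' @param contact_vib_sd Standard deviation of the rim-contact vibration on
#'   accelerometer channels during true propulsion (m/s^2).
#' @param contact_jolt Amplitude of the two-sample contact/release jolt on
#'   the vertical hand accelerometer (m/s^2).
#' @param dance_gyro_sd,dance_acc_sd Stationary standard deviation of the
#'   dance (Ornstein-Uhlenbeck) process on gyro / accel channels.
#' @param dance_tau_s Correlation time of the dance process (s).
#' @param burst_rate_hz Expected number of arm-wave bursts per second of
#'   dance.
#' @param burst_gyro_amp,burst_acc_amp Peak amplitude of arm-wave bursts.
#' @param gravity Gravity offset added to the vertical (Z) accelerometer
#'   axes (m/s^2).
#' @param trunk_surge Trunk forward-surge acceleration during propulsion
#'   (m/s^2).
#' @param trunk_yaw_amp Trunk yaw rate during clockwise/anticlockwise turns
#'   (deg/s).
#' @param fsr_analog If `TRUE` the FSR channels emulate an analog sensor
#'   (contact values jittered in (0.7, 1]); default is binary 0/1.
#' @return A `simulator_config` list.
#' @export
simulator_config <- function(fs_hz = 30, noise_sd = 1,
                             dance_gap_range = c(1, 3), seed = 1L,
                             duration_range_ms = c(600L, 1500L),
                             propulsion_gyro_amp = 150,
                             propulsion_acc_amp = 3,
                             fpg_scale = 0.9,
                             contact_vib_sd = 1.5,
                             contact_jolt = 4,
                             dance_gyro_sd = 18,
                             dance_acc_sd = 0.7,
                             dance_tau_s = 0.25,
                             burst_rate_hz = 0.2,
                             burst_gyro_amp = 45,
                             burst_acc_amp = 1.2,
                             gravity = 9.81,
                             trunk_surge = 0.5,
                             trunk_yaw_amp = 25,
                             fsr_analog = FALSE) {
  stopifnot(fs_hz > 0, noise_sd >= 0, length(dance_gap_range) == 2,
            dance_gap_range[1] <= dance_gap_range[2],
            duration_range_ms[1] <= duration_range_ms[2])
  structure(as.list(environment()), class = "simulator_config")
}

#' Generate a random choreography plan
#'
#' A choreography contains each of the eight propulsion gestures exactly
#' once plus (optionally) one fake propulsion gesture, in random order.
#' Gesture durations are uniform integers in the configured 600-1500 ms
#' range; each gesture is preceded (and the last followed) by dance filler
#' lasting `dance_gap_range` (default 1-3) times its duration.
#'
#' @param seed Integer seed; plans are deterministic given the seed.
#' @param include_fpg Include one fake propulsion gesture (default `TRUE`).
#' @param config A [simulator_config()].
#' @return A `choreography_plan`: list with `events` (data frame: `label`,
#'   `onset_ms`, `duration_ms`, `left_active`, `right_active`,
#'   `fsr_active`), `trial_length_ms`, `seed`, `include_fpg`.
#' @export
#' @examples
#' plan <- make_choreography(seed = 1)
#' plan$events$label
make_choreography <- function(seed, include_fpg = TRUE,
                              config = simulator_config()) {
  withr::local_seed(as.integer(seed))
  labels <- propulsion_gestures()
  if (include_fpg) {
    labels <- c(labels, paste0("fpg-", sample(propulsion_gestures(), 1)))
  }
  labels <- sample(labels)
  n_ev <- length(labels)
  dur <- sample(seq(config$duration_range_ms[1], config$duration_range_ms[2]),
                n_ev, replace = TRUE)
  gap_mult <- stats::runif(n_ev + 1L, config$dance_gap_range[1],
                           config$dance_gap_range[2])
  # gap i precedes event i and scales with that event's duration; the
  # trailing gap scales with the last event
  gaps <- round(gap_mult * dur[c(seq_len(n_ev), n_ev)])
  onset <- numeric(n_ev)
  t <- 0
  for (i in seq_len(n_ev)) {
    t <- t + gaps[i]
    onset[i] <- t
    t <- t + dur[i]
  }
  trial_length <- t + gaps[n_ev + 1L]
  sides <- lapply(labels, gesture_sides)
  events <- data.frame(
    label = labels,
    onset_ms = onset,
    duration_ms = dur,
    left_active = vapply(sides, function(s) "left" %in% s, logical(1)),
    right_active = vapply(sides, function(s) "right" %in% s, logical(1)),
    fsr_active = !grepl("^fpg-", labels),
    stringsAsFactors = FALSE
  )
  structure(list(events = events, trial_length_ms = trial_length,
                 seed = as.integer(seed), include_fpg = include_fpg),
            class = "choreography_plan")
}

#' @export
print.choreography_plan <- function(x, ...) {
  cat(sprintf("<choreography_plan> %d events over %.1f s (seed %d)\n",
              nrow(x$events), x$trial_length_ms / 1000, x$seed))
  invisible(x)
}

# Ornstein-Uhlenbeck-like smoothed noise with stationary sd `sd` and
# correlation time `tau_s`.
ou_process <- function(n, sd, tau_s, fs) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-1 / (fs * tau_s))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Dance-process channel: OU background plus sporadic sinusoidal arm-wave
# bursts with a raised-cosine envelope.
dance_channel <- function(n, sd, amp, config) {
  fs <- config$fs_hz
  x <- ou_process(n, sd, config$dance_tau_s, fs)
  n_burst <- stats::rpois(1, config$burst_rate_hz * n / fs)
  for (b in seq_len(n_burst)) {
    len <- round(stats::runif(1, 0.5, 1.5) * fs)
    start <- sample.int(max(1L, n - len), 1)
    idx <- start:min(n, start + len - 1L)
    tt <- seq_along(idx) / fs
    f <- stats::runif(1, 0.5, 2)
    env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
    x[idx] <- x[idx] + amp * stats::runif(1, 0.4, 1) * env *
      sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  }
  x
}

# Deterministic kinematic template of one propulsion-like gesture for one
# hand: half-sine angular-velocity pulse on the wheel-rotation axis (Y),
# correlated cross-axis rotation, biphasic tangential acceleration and a
# vertical acceleration bump. `dir` is +1 forward, -1 backward.
propulsion_template <- function(n_g, dir, scale, config) {
  tau <- seq(0, 1, length.out = n_g)
  p <- sin(pi * tau)
  list(
    acc_x = dir * config$propulsion_acc_amp * scale * sin(2 * pi * tau),
    acc_y = 0.3 * config$propulsion_acc_amp * scale * p,
    acc_z = 0.8 * scale * p,
    gyro_x = 0.25 * dir * config$propulsion_gyro_amp * scale * p,
    gyro_y = dir * config$propulsion_gyro_amp * scale * p,
    gyro_z = 0.1 * config$propulsion_gyro_amp * scale * p
  )
}

#' Synthesize a trial recording from a choreography plan
#'
#' Renders all 17 channels of the trial schema. Dance filler is an
#' Ornstein-Uhlenbeck process with arm-wave bursts on every hand channel;
#' propulsion and fake-propulsion segments replace the active hand's
#' channels with a deterministic kinematic template plus measurement
#' noise. The FSR channel of a propelling hand is high exactly over true
#' propulsion segments and zero during fake propulsions and dance, so FSR
#' boundaries and ground-truth annotations agree exactly for PGs.
#'
#' @param plan A [make_choreography()] plan.
#' @param config A [simulator_config()]; `config$seed` drives all synthesis
#'   randomness.
#' @return List with `recording` (a [trial_recording()]) and `annotations`
#'   (data frame of ground-truth gesture boundaries, snapped to the sample
#'   grid, with `source = "synthetic"`).
#' @export
synthesize_trial <- function(plan, config = simulator_config()) {
  stopifnot(inherits(plan, "choreography_plan"))
  withr::local_seed(as.integer(config$seed))
  fs <- config$fs_hz
  n <- floor(plan$trial_length_ms * fs / 1000) + 1L
  t_ms <- round(1000 * (0:(n - 1L)) / fs)
  ev <- plan$events
  if (any(ev$onset_ms + ev$duration_ms > plan$trial_length_ms)) {
    stop("plan events exceed trial_length_ms")
  }

  ch <- list()
  for (s in c("l", "r")) {
    ch[[paste0(s, "_acc_x")]] <- dance_channel(n, config$dance_acc_sd,
                                               config$burst_acc_amp, config)
    ch[[paste0(s, "_acc_y")]] <- dance_channel(n, config$dance_acc_sd,
                                               config$burst_acc_amp, config)
    ch[[paste0(s, "_acc_z")]] <- config$gravity +
      dance_channel(n, config$dance_acc_sd, config$burst_acc_amp, config)
    ch[[paste0(s, "_gyro_x")]] <- dance_channel(n, config$dance_gyro_sd,
                                                config$burst_gyro_amp, config)
    ch[[paste0(s, "_gyro_y")]] <- dance_channel(n, config$dance_gyro_sd,
                                                config$burst_gyro_amp, config)
    ch[[paste0(s, "_gyro_z")]] <- dance_channel(n, config$dance_gyro_sd,
                                                config$burst_gyro_amp, config)
    ch[[paste0(s, "_fsr")]] <- numeric(n)
  }
  ch$trunk_acc_z <- config$gravity +
    0.4 * dance_channel(n, config$dance_acc_sd, config$burst_acc_amp, config)
  ch$trunk_gyro <- 0.4 * dance_channel(n, config$dance_gyro_sd,
                                       config$burst_gyro_amp, config)

  ann <- ev[0, ]
  ann$onset_ms <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    start <- which(t_ms >= ev$onset_ms[i])[1]
    n_g <- max(2L, round(ev$duration_ms[i] * fs / 1000))
    if (start + n_g > n) stop("plan events exceed trial_length_ms")
    idx <- start:(start + n_g - 1L)
    is_fpg <- !ev$fsr_active[i]
    scale <- if (is_fpg) config$fpg_scale else 1
    for (side in c("left", "right")) {
      active <- if (side == "left") ev$left_active[i] else ev$right_active[i]
      if (!active) next
      pre <- if (side == "left") "l_" else "r_"
      dir <- if (side_basic_label(ev$label[i], side) == "forward") 1 else -1
      tpl <- propulsion_template(n_g, dir, scale, config)
      ch[[paste0(pre, "acc_x")]][idx] <- tpl$acc_x
      ch[[paste0(pre, "acc_y")]][idx] <- tpl$acc_y
      ch[[paste0(pre, "acc_z")]][idx] <- config$gravity + tpl$acc_z
      ch[[paste0(pre, "gyro_x")]][idx] <- tpl$gyro_x
      ch[[paste0(pre, "gyro_y")]][idx] <- tpl$gyro_y
      ch[[paste0(pre, "gyro_z")]][idx] <- tpl$gyro_z
      if (!is_fpg) {
        # rim contact: broadband vibration plus contact/release jolts
        for (ax in c("acc_x", "acc_y", "acc_z")) {
          ch[[paste0(pre, ax)]][idx] <- ch[[paste0(pre, ax)]][idx] +
            stats::rnorm(n_g, 0, config$contact_vib_sd)
        }
        j <- config$contact_jolt
        ch[[paste0(pre, "acc_z")]][idx[1:2]] <-
          ch[[paste0(pre, "acc_z")]][idx[1:2]] + c(j, -j / 2)
        ch[[paste0(pre, "acc_z")]][idx[(n_g - 1L):n_g]] <-
          ch[[paste0(pre, "acc_z")]][idx[(n_g - 1L):n_g]] + c(-j / 2, j)
        fsr_val <- if (config$fsr_analog) stats::runif(n_g, 0.7, 1) else 1
        ch[[paste0(pre, "fsr")]][idx] <- fsr_val
      }
    }
    base <- sub("^fpg-", "", ev$label[i])
    ch$trunk_acc_z[idx] <- ch$trunk_acc_z[idx] +
      config$trunk_surge * sin(pi * seq(0, 1, length.out = n_g))
    if (base %in% c("clockwise", "anticlockwise")) {
      yaw <- if (base == "clockwise") -1 else 1
      ch$trunk_gyro[idx] <- ch$trunk_gyro[idx] +
        yaw * config$trunk_yaw_amp * sin(pi * seq(0, 1, length.out = n_g))
    }
    end_ms <- if (start + n_g <= n) t_ms[start + n_g] else
      t_ms[n] + round(1000 / fs)
    ann_i <- ev[i, ]
    ann_i$onset_ms <- t_ms[start]
    ann_i$duration_ms <- end_ms - t_ms[start]
    ann <- rbind(ann, ann_i)
  }

  # measurement noise on the inertial channels only
  if (config$noise_sd > 0) {
    for (nm in names(ch)) {
      base_sd <- if (grepl("gyro", nm)) 3 else if (grepl("acc", nm)) 0.15 else 0
      if (base_sd > 0) {
        ch[[nm]] <- ch[[nm]] + stats::rnorm(n, 0, base_sd * config$noise_sd)
      }
    }
  }

  df <- data.frame(ch, t_ms = t_ms, check.names = FALSE)
  ann$source <- rep("synthetic", nrow(ann))
  rownames(ann) <- NULL
  list(recording = trial_recording(df[, trial_channels()], fs_hz = fs),
       annotations = ann)
}

#' Simulate a corpus of choreography trials
#'
#' Emulates the standard acquisition protocol: each simulated subject is
#' assigned one random choreography (eight propulsion gestures plus one
#' fake propulsion, in subject-specific random order) and repeats it
#' `trials_per_subject` times with independent noise and dance
#' improvisation.
#'
#' @param n_subjects Number of simulated subjects (default 8).
#' @param trials_per_subject Repetitions of each subject's choreography
#'   (default 10).
#' @param seed Integer master seed; all plan and trial seeds derive from it.
#' @param config A [simulator_config()] (its `seed` field is overridden per
#'   trial).
#' @param include_fpg Include a fake propulsion in each choreography.
#' @return List of trials, each a list with `recording`, `annotations`,
#'   `subject`, `trial`.
#' @export
simulate_corpus <- function(n_subjects = 8, trials_per_subject = 10,
                            seed = 1L, config = simulator_config(),
                            include_fpg = TRUE) {
  seed <- as.integer(seed) %% 1000000L
  out <- vector("list", n_subjects * trials_per_subject)
  k <- 0L
  for (p in seq_len(n_subjects)) {
    plan <- make_choreography(seed + 7919L * p, include_fpg = include_fpg,
                              config = config)
    for (tr in seq_len(trials_per_subject)) {
      cfg <- config
      cfg$seed <- seed + 7919L * p + 131L * tr
      syn <- synthesize_trial(plan, cfg)
      k <- k + 1L
      out[[k]] <- list(recording = syn$recording,
                       annotations = syn$annotations,
                       subject = p, trial = tr)
    }
  }
  out
}

#' Write a simulated corpus to a directory
#'
#' One CSV trial file plus one JSON annotation sidecar per trial, named
#' `subject<p>_trial<t>.csv` / `.json`.
#'
#' @param corpus Output of [simulate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Character vector of trial file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(corpus))
  for (i in seq_along(corpus)) {
    tr <- corpus[[i]]
    stem <- file.path(dir, sprintf("subject%d_trial%d", tr$subject, tr$trial))
    write_trial(tr$recording, paste0(stem, ".csv"))
    write_annotations(tr$annotations, paste0(stem, ".json"))
    paths[i] <- paste0(stem, ".csv")
  }
  invisible(paths)
}

#' Read a simulated corpus from a directory
#'
#' @param dir Directory written by [write_corpus()].
#' @return List of trials (`recording`, `annotations`, `subject`, `trial`).
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "^subject[0-9]+_trial[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no trial files found in ", dir)
  lapply(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^subject([0-9]+)_trial([0-9]+)", basename(f)))[[1]]
    list(recording = read_trial(f),
         annotations = read_annotations(sub("\\.csv$", ".json", f)),
         subject = as.integer(m[2]), trial = as.integer(m[3]))
  })
}
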