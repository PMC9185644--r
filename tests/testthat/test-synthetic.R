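# Synthetic choreography generator: composition, determinism, and the
# contact-based ground-truth contract.

test_that("choreography plans are deterministic and contain 8 PGs + 1 FPG", {
  p1 <- make_choreography(seed = 1)
  p2 <- make_choreography(seed = 1)
  expect_identical(p1, p2)

  ev <- p1$events
  expect_equal(nrow(ev), 9)
  pg <- ev$label[!grepl("^fpg-", ev$label)]
  expect_setequal(pg, propulsion_gestures())
  expect_equal(sum(grepl("^fpg-", ev$label)), 1)

  p0 <- make_choreography(seed = 1, include_fpg = FALSE)
  expect_equal(nrow(p0$events), 8)
  expect_setequal(p0$events$label, propulsion_gestures())
})

test_that("different seeds give differently ordered choreographies", {
  # identical orderings have probability 1/9! ~ 3e-6; these two seeds differ
  p1 <- make_choreography(seed = 1)
  p2 <- make_choreography(seed = 2)
  expect_false(identical(p1$events$label, p2$events$label))
})

test_that("plan durations and dance gaps respect the study conditions", {
  for (seed in 1:5) {
    p <- make_choreography(seed)
    ev <- p$events
    expect_true(all(ev$duration_ms >= 600 & ev$duration_ms <= 1500))
    # events are ordered and separated by dance gaps of 1-3x the
    # following propulsion's duration
    gaps <- diff(c(0, ev$onset_ms)) - c(0, head(ev$duration_ms, -1))
    ratio <- gaps / ev$duration_ms
    expect_true(all(ratio >= 1 - 1e-3 & ratio <= 3 + 1e-3))
    # bilateral gestures engage both arms, unilateral exactly one
    base <- sub("^fpg-", "", ev$label)
    bilateral <- base %in% c("forward", "backward", "clockwise",
                             "anticlockwise")
    expect_equal(ev$left_active & ev$right_active, bilateral)
    expect_true(all(xor(ev$left_active, ev$right_active) == !bilateral))
  }
})

test_that("synthesis is deterministic given the seed", {
  plan <- make_choreography(seed = 3)
  cfg <- simulator_config(seed = 11, noise_sd = 0)
  s1 <- synthesize_trial(plan, cfg)
  s2 <- synthesize_trial(plan, cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$annotations, s2$annotations)
  # with measurement noise, still deterministic given the same seed
  cfgn <- simulator_config(seed = 11)
  expect_identical(synthesize_trial(plan, cfgn)$recording$data,
                   synthesize_trial(plan, cfgn)$recording$data)
})

test_that("trials follow the 17-channel schema and 30 Hz grid", {
  syn <- synthesize_trial(make_choreography(4), simulator_config(seed = 2))
  expect_identical(names(syn$recording$data), trial_channels())
  expect_equal(syn$recording$fs_hz, 30)
  expect_true(all(diff(syn$recording$data$t_ms) > 0))
})

test_that("FSR boundaries agree exactly with PG annotations, FPGs are silent", {
  for (seed in c(2, 9)) {
    syn <- synthesize_trial(make_choreography(seed),
                            simulator_config(seed = seed + 100))
    ann <- syn$annotations
    for (side in c("left", "right")) {
      active <- if (side == "left") ann$left_active else ann$right_active
      pg <- ann[ann$fsr_active & active, ]
      b <- fsr_boundaries(syn$recording, side)
      expect_equal(b$onset_ms, pg$onset_ms)
      expect_equal(b$offset_ms, pg$onset_ms + pg$duration_ms)
      # fake propulsions never overlap a contact interval
      fpg <- ann[!ann$fsr_active & active, ]
      for (i in seq_len(nrow(fpg))) {
        expect_false(any(b$onset_ms < fpg$onset_ms[i] + fpg$duration_ms[i] &
                           b$offset_ms > fpg$onset_ms[i]))
      }
    }
  }
})

test_that("inactive hand carries only the dance process during unilateral gestures", {
  cfg <- simulator_config(seed = 5, noise_sd = 0)
  syn <- synthesize_trial(make_choreography(1), cfg)
  ann <- syn$annotations
  uni <- ann[xor(ann$left_active, ann$right_active), ]
  t_ms <- syn$recording$data$t_ms
  for (i in seq_len(nrow(uni))) {
    idle <- if (uni$left_active[i]) "r_gyro_y" else "l_gyro_y"
    span <- t_ms >= uni$onset_ms[i] & t_ms < uni$onset_ms[i] + uni$duration_ms[i]
    # dance process stays well below the propulsion pulse peak
    expect_lt(max(abs(syn$recording$data[[idle]][span])),
              0.8 * cfg$propulsion_gyro_amp)
  }
})

test_that("noise-free gesture templates are recoverable by matched filtering", {
  cfg <- simulator_config(seed = 8, noise_sd = 0)
  syn <- synthesize_trial(make_choreography(6), cfg)
  ann <- syn$annotations
  t_ms <- syn$recording$data$t_ms
  pg <- ann[ann$fsr_active, ]
  picked <- pg[c(1, 3, 5), ]
  for (i in seq_len(nrow(picked))) {
    side <- if (picked$left_active[i]) "left" else "right"
    sig <- syn$recording$data[[if (side == "left") "l_gyro_y" else "r_gyro_y"]]
    start <- which(t_ms == picked$onset_ms[i])
    n_g <- round(picked$duration_ms[i] * 30 / 1000)
    dir <- if (side_basic_label(picked$label[i], side) == "forward") 1 else -1
    tpl <- dir * cfg$propulsion_gyro_amp * sin(pi * seq(0, 1, length.out = n_g))
    # normalized cross-correlation: exactly 1 at the true template location
    xc <- vapply(seq_len(length(sig) - n_g + 1L), function(a) {
      seg <- sig[a:(a + n_g - 1L)]
      den <- sqrt(sum(seg^2) * sum(tpl^2))
      if (den == 0) 0 else sum(seg * tpl) / den
    }, numeric(1))
    expect_equal(which.max(xc), start)
    expect_equal(max(xc), 1, tolerance = 1e-12)
  }
})

test_that("oversized plans are rejected", {
  plan <- make_choreography(1)
  plan$trial_length_ms <- plan$events$onset_ms[9] - 1
  expect_error(synthesize_trial(plan, simulator_config(seed = 1)),
               "exceed")
})
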