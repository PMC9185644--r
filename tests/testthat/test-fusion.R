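# Bilateral fusion table, spike filtering, event extraction, and timing
# metrics.

test_that("fusion maps all nine label pairs to the canonical gestures", {
  expected <- rbind(
    c("forward",  "dance",    "left-forward",   "1"),
    c("backward", "dance",    "left-backward",  "2"),
    c("dance",    "forward",  "right-forward",  "3"),
    c("dance",    "backward", "right-backward", "4"),
    c("forward",  "forward",  "forward",        "5"),
    c("backward", "backward", "backward",       "6"),
    c("forward",  "backward", "clockwise",      "7"),
    c("backward", "forward",  "anticlockwise",  "8"),
    c("dance",    "dance",    "dance",          "9"))
  for (i in seq_len(nrow(expected))) {
    g <- unname(fuse(expected[i, 1], expected[i, 2]))
    expect_equal(g, expected[i, 3])
    expect_equal(gesture_id(g), as.integer(expected[i, 4]))
  }
  expect_error(fuse("forward", "sideways"), "unknown")
})

test_that("despike removes sub-50 ms gestures, keeps longer ones, is idempotent", {
  tl <- make_timeline(c("dance", "clockwise", "dance"),
                      c(0, 500, 533), c(500, 533, 1000))
  d <- despike(tl)
  expect_equal(nrow(d), 1)
  expect_equal(as.character(d$gesture), "dance")
  expect_equal(d$start_ms, 0)
  expect_equal(d$end_ms, 1000)

  tl66 <- make_timeline(c("dance", "forward", "dance"),
                        c(0, 500, 566), c(500, 566, 1000))
  d66 <- despike(tl66)
  expect_equal(as.character(d66$gesture), c("dance", "forward", "dance"))

  expect_identical(despike(despike(tl66)), despike(tl66))
})

test_that("despike never adds segments or labels", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      labs <- sample(c(propulsion_gestures(), "dance"), n, replace = TRUE)
      labs <- labs[c(TRUE, diff(as.integer(factor(labs))) != 0)]
      bounds <- sort(sample(seq(0, 3000, by = 33), length(labs) + 1))
      tl <- make_timeline(labs, head(bounds, -1), tail(bounds, -1))
      d <- despike(tl)
      expect_lte(sum(d$gesture != "dance"), sum(tl$gesture != "dance"))
      expect_true(all(d$gesture %in% c(tl$gesture, "dance")))
      expect_true(all(d$end_ms - d$start_ms >= 50 | d$gesture == "dance"))
      # segments tile the span with no equal neighbors
      expect_equal(d$start_ms[-1], d$end_ms[-nrow(d)])
      if (nrow(d) > 1) {
        expect_true(all(d$gesture[-1] != d$gesture[-nrow(d)]))
      }
    }
  })
})

test_that("events are one per maximal non-dance segment, ordered", {
  tl <- make_timeline(
    c("dance", "forward", "dance", "left-backward", "dance"),
    c(0, 1000, 2000, 3000, 4000),
    c(1000, 2000, 3000, 4000, 5000))
  ev <- extract_events(tl)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$gesture, c("forward", "left-backward"))
  expect_equal(ev$gesture_id, c(5L, 2L))
  expect_equal(ev$onset_ms, c(1000, 3000))
  expect_equal(ev$duration_ms, c(1000, 1000))
  expect_equal(nrow(extract_events(make_timeline("dance", 0, 5000))), 0)
})

test_that("score_timing is exact for perfect predictions and flags extras", {
  ref <- data.frame(onset_ms = c(1000, 5000, 9000),
                    duration_ms = c(800, 900, 1000))
  st <- score_timing(ref, ref)
  expect_equal(st$mae_ms, 0)
  expect_equal(st$mean_duration_error_pct, 0)
  expect_equal(st$n_unmatched_events, 0)

  ev <- rbind(ref, data.frame(onset_ms = 20000, duration_ms = 100))
  st2 <- score_timing(ev, ref)
  expect_equal(st2$n_unmatched_events, 1)
  expect_equal(st2$n_unmatched_reference, 0)
  expect_equal(st2$mae_ms, 0)
  expect_error(score_timing(ev, ref[0, ]), "empty reference")
})

test_that("onset errors are signed pred - ref (negative = early)", {
  ref <- data.frame(onset_ms = c(1000, 3000), duration_ms = c(500, 500))
  ev <- data.frame(onset_ms = c(940, 3210), duration_ms = c(400, 600))
  st <- score_timing(ev, ref)
  expect_equal(st$matched$onset_error_ms, c(-60, 210))
  expect_equal(st$mae_ms, 135)
  expect_equal(st$matched$duration_error_pct, c(20, 20))
})

test_that("prediction streams are contiguous and label every window", {
  models <- tiny_models()
  tr <- tiny_corpus()[[2]]
  ps <- predict_stream(tr$recording, models$right)
  p <- models$right$window_params
  expect_equal(nrow(ps), count_windows(nrow(tr$recording$data), p))
  expect_true(all(as.character(ps$label) %in% basic_labels()))
  expect_equal(ps$start_ms[-1], ps$end_ms[-nrow(ps)])
  # per-sample replay covers at least the same span, more finely
  ps1 <- predict_stream(tr$recording, models$right, step = 1)
  expect_gte(ps1$end_ms[nrow(ps1)], ps$end_ms[nrow(ps)])
  expect_gt(nrow(ps1), nrow(ps))
  expect_equal(ps1$start_ms[-1], ps1$end_ms[-nrow(ps1)])
})

test_that("a propulsion-free recording replays as (almost) all dance", {
  plan <- make_choreography(5)
  plan$events <- plan$events[0, ]
  syn <- synthesize_trial(plan, simulator_config(seed = 17))
  models <- tiny_models()
  ps <- predict_stream(syn$recording, models$left)
  expect_gt(mean(ps$label == "dance"), 0.9)
})

test_that("mismatched window grids cannot be fused", {
  models <- tiny_models()
  tr <- tiny_corpus()[[1]]
  a <- predict_stream(tr$recording, models$left)
  b <- predict_stream(tr$recording, models$right, step = 1)
  expect_error(fuse_streams(a, b), "not aligned")
})
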