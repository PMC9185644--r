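# Sliding windows, the 70% labeling rule, and balanced dataset assembly.

test_that("count_windows matches the closed form and enumeration", {
  expect_equal(count_windows(300, window_params(30, 5)), 55)
  expect_equal(count_windows(30, window_params(30, 5)), 1)
  # brute force: admissible start offsets are multiples of s up to n - w
  expect_equal(count_windows(40, window_params(30, 5)),
               sum((0:(40 - 30)) %% 5 == 0))
  expect_equal(count_windows(40, window_params(30, 5)), 3)
  expect_error(count_windows(20, window_params(30, 5)), "empty-trial")
})

test_that("count_windows equals enumeration for all small (n, w, s)", {
  bad <- character(0)
  for (n in c(1:40, 60)) {
    for (w in 1:n) {
      for (s in 1:w) {
        if (count_windows(n, window_params(w, s)) !=
            sum((0:(n - w)) %% s == 0)) {
          bad <- c(bad, sprintf("n=%d w=%d s=%d", n, w, s))
        }
      }
    }
  }
  expect_identical(bad, character(0))
})

test_that("slide covers [k*s, k*s + w) and agrees with count_windows", {
  rec <- make_rec(100, fs = 1000)
  withr::with_seed(3, {
    for (rep in 1:10) {
      w <- sample(2:40, 1)
      s <- sample(1:w, 1)
      p <- window_params(w, s)
      wins <- slide(rec, p)
      expect_equal(nrow(wins), count_windows(100, p))
      expect_equal(wins$start_sample, wins$k * s + 1)
      expect_equal(wins$end_sample - wins$start_sample, rep(w, nrow(wins)))
    }
  })
  # s = w tiles the prefix without overlap
  wins <- slide(rec, window_params(20, 20))
  expect_equal(wins$start_sample, seq(1, 81, by = 20))
  # w = 30, s = 5: consecutive windows share w - s = 25 samples
  wins <- slide(rec, window_params(30, 5))
  shared <- wins$end_sample[-nrow(wins)] - wins$start_sample[-1]
  expect_true(all(shared == 25))
})

test_that("window labeling implements the three containment/overlap cases", {
  rec <- make_rec(60, fs = 1000)          # sample index == ms
  win <- slide(rec, window_params(30, 5))[1, , drop = FALSE]  # [0, 30)

  # case 1: window contains the whole gesture
  expect_equal(label_window(rec, win, side_ann("forward", 5, 20)), "forward")
  # case 2: gesture contains the whole window
  expect_equal(label_window(rec, win, side_ann("backward", -40, 140)),
               "backward")
  # case 3: overlap of exactly 21/30 samples passes, 20/30 does not
  expect_equal(label_window(rec, win, side_ann("forward", 9, 31)), "forward")
  expect_equal(label_window(rec, win, side_ann("forward", 10, 30)), "dance")
  # no annotations at all
  expect_equal(label_window(rec, win, side_ann(character(0), numeric(0),
                                               numeric(0))), "dance")
})

test_that("labeling is order-invariant and flags contradictory overlaps", {
  rec <- make_rec(60, fs = 1000)
  win <- slide(rec, window_params(30, 5))[1, , drop = FALSE]
  ann <- side_ann(c("forward", "backward"), c(5, 40), c(20, 15))
  ann_rev <- ann[2:1, ]
  expect_equal(label_window(rec, win, ann),
               label_window(rec, win, ann_rev))
  # two fully-contained gestures with different labels cannot be resolved
  conflict <- side_ann(c("forward", "backward"), c(2, 16), c(10, 10))
  expect_error(label_window(rec, win, conflict), "conflict")
})

test_that("growing overlap never flips a window label from gesture to dance", {
  rec <- make_rec(80, fs = 1000)
  win <- slide(rec, window_params(30, 5))[2, , drop = FALSE]  # [5, 35)
  seen <- character(0)
  for (len in 1:40) {                    # gesture [35 - len, 45) grows left
    lab <- label_window(rec, win, side_ann("forward", 35 - len, len + 10))
    seen <- c(seen, lab)
  }
  # dance for small overlaps, forward from the 70% threshold on, no flip back
  expect_true(all(seen[1:20] == "dance"))
  expect_true(all(seen[21:40] == "forward"))
})

test_that("dance undersampling balances to max(forward, backward)", {
  y <- factor(rep(c("forward", "backward", "dance"), c(708, 749, 5000)),
              levels = basic_labels())
  idx <- propulse:::balance_classes(y, seed = 1)
  expect_equal(as.vector(table(y[idx])), c(708, 749, 749))
  expect_identical(propulse:::balance_classes(y, seed = 1), idx)
  expect_false(identical(propulse:::balance_classes(y, seed = 2), idx))
})

test_that("build_dataset pools trials, balances classes and is seeded", {
  corpus <- tiny_corpus()
  ds <- build_dataset(corpus, "right", "two-sensor", window_params(30, 5),
                      seed = 1)
  k <- ds$counts$kept
  expect_equal(unname(k["dance"]), max(k["forward"], k["backward"]))
  expect_equal(ncol(ds$X), 152)
  expect_equal(nrow(ds$X), length(ds$y))
  expect_equal(length(ds$groups), length(ds$y))
  ds2 <- build_dataset(corpus, "right", "two-sensor", window_params(30, 5),
                       seed = 1)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$y, ds2$y)
})

test_that("a corpus without propulsion windows is rejected", {
  corpus <- tiny_corpus()[1]
  # strip every FSR-backed annotation: all windows become dance
  corpus[[1]]$annotations$fsr_active <- FALSE
  expect_error(
    build_dataset(corpus, "left", "two-sensor", window_params(30, 5)),
    "degenerate-dataset")
})
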