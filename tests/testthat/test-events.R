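test_that("zero force raises an empty-events error", {
  t <- seq(0, 5, by = 0.01)
  expect_error(detect_events(t, matrix(0, length(t), 2)), "no force crossings")
})

test_that("rectangular force pulses yield events at the pulse edges", {
  t <- seq(0, 10, by = 0.01)
  f <- matrix(0, length(t), 2)
  # 0.6 s stance at 1 Hz on both feet, right shifted by 0.5 s
  for (k in 0:8) {
    f[t >= k & t < k + 0.6, 1] <- 700
    f[t >= k + 0.5 & t < k + 1.1, 2] <- 700
  }
  ev <- detect_events(t, f, threshold_n = 30)
  expect_lt(max(abs(ev$hs$L - 1:8)), 0.011)
  expect_lt(max(abs(ev$to$L - ((0:8) + 0.6))), 0.011)
  # alternation HS, TO per foot
  for (s in c("L", "R")) {
    evs <- sort(c(ev$hs[[s]], ev$to[[s]]))
    lab <- ifelse(evs %in% ev$hs[[s]], "HS", "TO")
    expect_true(all(lab[-1] != lab[-length(lab)]))
  }
})

test_that("brief unloading spikes are debounced", {
  t <- seq(0, 2, by = 0.01)
  f <- matrix(0, length(t), 2)
  f[t >= 0.2 & t < 1.2, ] <- 600
  f[t >= 0.6 & t < 0.63, ] <- 0    # 30 ms drop-out, below the 50 ms debounce
  ev <- detect_events(t, f)
  expect_length(ev$hs$L, 1L)
  expect_length(ev$to$L, 1L)
})

test_that("stride segmentation produces phase bounds that partition stance", {
  ev <- structure(list(
    hs = list(L = c(0, 1.1, 2.2, 3.3), R = c(0.55, 1.65, 2.75)),
    to = list(L = c(0.68, 1.78, 2.88), R = c(0.13, 1.23, 2.33, 3.43))),
    class = "gait_events")
  st <- segment_strides(ev, "L")
  expect_equal(nrow(st), 3L)
  expect_true(all(st$usable))
  # IDS + SS + TDS spans exactly the stance
  expect_equal((st$ids_end - st$start) + (st$ss_end - st$ids_end) +
                 (st$stance_end - st$ss_end), st$stance_end - st$start)
  expect_true(all(st$ids_end < st$ss_end & st$ss_end < st$stance_end))
})

test_that("strides lacking contralateral events are flagged unusable", {
  ev <- structure(list(hs = list(L = c(0, 1.1, 2.2), R = numeric(0)),
                       to = list(L = c(0.68, 1.78), R = numeric(0))),
                  class = "gait_events")
  st <- segment_strides(ev, "L")
  expect_equal(nrow(st), 2L)
  expect_false(any(st$usable))
  expect_error(segment_strides(structure(list(hs = list(L = 1, R = 1),
                                              to = list(L = 2, R = 2)),
                                         class = "gait_events"), "L"),
               "at least 2")
})

test_that("generated gait recovers the commanded phase schedule", {
  an <- quick_anthro()
  cfg <- gait_config(an, stance_fraction = 0.6, double_support_fraction = 0.1,
                     noise_scale = 0)
  g <- generate_trial(cfg, NULL, seed = 9)
  tr <- synchronize(g$trial)
  ev <- detect_events(tr$insole$time, tr$insole$force)
  st <- segment_strides(ev, "L")
  T <- g$truth$stride_period
  # IDS and TDS each last 10% of the cycle, within one sample
  expect_lt(max(abs((st$ids_end - st$start) - 0.1 * T)), 0.011)
  expect_lt(max(abs((st$stance_end - st$ss_end) - 0.1 * T)), 0.011)
})

test_that("disturbed and following strides are flagged; boundary onsets go to the later stride", {
  st <- data.frame(stride = 1:4, start = c(0, 1, 2, 3), end = c(1, 2, 3, 4))
  d <- list(onset = 1.5, duration = 0.2)
  out <- mark_disturbed(st, d)
  expect_equal(which(out$disturbed), 2L)
  expect_equal(which(out$excluded), 3L)
  out0 <- mark_disturbed(st, NULL)
  expect_false(any(out0$disturbed) || any(out0$excluded))
  # half-open intervals: onset exactly at a boundary belongs to the later stride
  outb <- mark_disturbed(st, list(onset = 2, duration = 0.2))
  expect_equal(which(outb$disturbed), 3L)
  expect_warning(mark_disturbed(st, list(onset = 99, duration = 0.2)),
                 "outside")
})

test_that("time normalization preserves endpoints and is scale-invariant", {
  tt <- seq(2, 3.2, by = 0.01)
  expect_equal(time_normalize(tt, rep(5, length(tt)), 2, 3.2),
               rep(5, 101))
  ramp <- 4 * (tt - 2)
  tn <- time_normalize(tt, ramp, 2, 3.2)
  expect_equal(tn[1], 0); expect_equal(tn[101], 4 * 1.2)
  expect_equal(tn, seq(0, 4.8, length.out = 101), tolerance = 1e-9)
  y <- sin(2 * pi * (tt - 2) / 1.2)
  tn2 <- time_normalize(tt, y, 2, 3.2)
  expect_lt(max(abs(tn2 - sin(2 * pi * seq(0, 1, length.out = 101)))), 1e-3)
  # invariance to uniform time re-scaling
  tn3 <- time_normalize(10 * tt, y, 20, 32)
  expect_equal(tn3, tn2, tolerance = 1e-9)
  expect_error(time_normalize(tt, y, 1.5, 3.2), "cover")
})
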