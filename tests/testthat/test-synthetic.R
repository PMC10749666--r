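test_that("identical seeds give bit-identical trials", {
  cfg <- gait_config(quick_anthro())
  d <- disturbance_spec("flexion", "SS", 2)
  pc <- perception_config()
  g1 <- generate_trial(cfg, d, seed = 101, perception_cfg = pc)
  g2 <- generate_trial(cfg, d, seed = 101, perception_cfg = pc)
  expect_identical(g1$trial$kin, g2$trial$kin)
  expect_identical(g1$trial$insole, g2$trial$insole)
  expect_identical(g1$trial$perception, g2$trial$perception)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_trial(cfg, d, seed = 102, perception_cfg = pc)
  expect_false(identical(g1$trial$kin$pos_x, g3$trial$kin$pos_x))
})

test_that("generated velocities are the derivatives of generated positions", {
  cfg <- gait_config(quick_anthro(), noise_scale = 0)
  g <- generate_trial(cfg, NULL, seed = 1, fs_kin = 600)
  k <- g$trial$kin
  dt <- 1 / 600
  n <- length(k$time); i <- 3:(n - 2)
  # 4th-order central differences
  d4 <- function(x) (-x[i + 2, ] + 8 * x[i + 1, ] - 8 * x[i - 1, ] +
                       x[i - 2, ]) / (12 * dt)
  rel <- function(num, ref) sqrt(mean((num - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rel(d4(k$pos_x), k$vel_x[i, ]), 1e-6)
  expect_lt(rel(d4(k$pos_z), k$vel_z[i, ]), 1e-6)
  expect_lt(rel(d4(k$orient), k$angvel[i, ]), 1e-6)
})

test_that("noise-free gait is periodic stride to stride", {
  zm <- zero_noise_metrics()
  for (m in names(zm$m$traj)) {
    a <- zm$m$traj[[m]][3, ]; b <- zm$m$traj[[m]][5, ]
    ok <- is.finite(a) & is.finite(b)
    expect_lt(max(abs(a[ok] - b[ok])) / diff(range(a[ok])), 1e-8)
  }
})

test_that("the disturbance alters the knee channel only inside its 200 ms window", {
  cfg <- gait_config(quick_anthro(), noise_scale = 0)
  g0 <- generate_trial(cfg, NULL, seed = 42)
  g1 <- generate_trial(cfg, disturbance_spec("flexion", "SS", 3), seed = 42)
  tt <- g1$trial$knee$time
  on <- g1$trial$disturbance$onset
  dif <- abs(g1$trial$knee$angle - g0$trial$knee$angle)
  expect_equal(max(dif[tt < on | tt > on + 0.2]), 0)
  expect_gt(max(dif[tt >= on & tt <= on + 0.2]), 0.1)
  # flexion and extension pulses have opposite signs, amplitude grows with level
  expect_gt(disturbance_spec("flexion", "IDS", 2)$amplitude, 0)
  expect_lt(disturbance_spec("extension", "IDS", 2)$amplitude, 0)
  amps <- vapply(1:3, function(i)
    disturbance_spec("flexion", "IDS", i)$amplitude, numeric(1))
  expect_true(all(diff(amps) > 0))
  expect_error(disturbance_spec("flexion", "IDS", 1, duration = 0.3))
})

test_that("ground-truth events and phases are recovered at zero noise", {
  cfg <- gait_config(quick_anthro(), noise_scale = 0)
  for (s in 1:5) {
    g <- generate_trial(cfg, NULL, seed = s)
    tr <- synchronize(g$trial)
    ev <- detect_events(tr$insole$time, tr$insole$force)
    for (f in c("L", "R")) {
      expect_lt(max(abs(ev$hs[[f]] - g$truth$events$hs[[f]])), 0.01)
      expect_lt(max(abs(ev$to[[f]] - g$truth$events$to[[f]])), 0.01)
    }
    st <- segment_strides(ev, "L")
    expect_lt(max(abs(st$ids_end - g$truth$strides$ids_end)), 0.01)
    expect_lt(max(abs(st$ss_end - g$truth$strides$ss_end)), 0.01)
    expect_lt(max(abs(st$stance_end - g$truth$strides$stance_end)), 0.01)
  }
})

test_that("cohort schedules cover the condition grid with per-trial seeds", {
  coh <- generate_cohort(n_subjects = 7, n_trials = 168, seed = 5)
  expect_length(coh$subjects, 7L)
  for (su in coh$subjects) {
    expect_equal(nrow(su$schedule), 168L)
    tab <- table(su$schedule$type, su$schedule$timing, su$schedule$intensity)
    expect_true(all(tab == 14L))
    expect_equal(anyDuplicated(su$schedule$seed), 0L)
  }
  # deterministic regeneration of a scheduled trial
  r1 <- realize_trial(coh, 2, 5)
  r2 <- realize_trial(coh, 2, 5)
  expect_identical(r1$trial$kin$pos_x, r2$trial$kin$pos_x)
  expect_error(generate_cohort(n_trials = 100), "%%")
})

test_that("zero latent coupling decouples perception from the gait deviation", {
  coh <- generate_cohort(n_subjects = 1, n_trials = 96, seed = 31,
                         coupling = 0)
  su <- coh$subjects[[1]]
  amp <- per <- numeric(0)
  for (k in seq_len(96)) {
    r <- realize_trial(coh, 1, k)
    amp <- c(amp, abs(r$truth$amplitude_realized))
    per <- c(per, perception_levels(r$trial$perception)$level)
  }
  expect_lt(abs(kendall_tau(amp, per)$tau), 2 / sqrt(96))
})

test_that("strong coupling with tight thresholds maps intensity onto levels monotonically", {
  # cut-points placed between the intensity amplitudes 1.5 / 3.0 / 4.5
  pc <- perception_config(coupling = 1, thresholds = c(1.0, 2.2, 3.7),
                          noise_sd = 0.05)
  cfg <- gait_config(quick_anthro(), noise_scale = 0)
  hits <- 0L; n <- 0L
  for (i in 1:3) for (s in 1:10) {
    g <- generate_trial(cfg, disturbance_spec("extension", "IDS", i),
                        seed = s, perception_cfg = pc)
    lev <- perception_levels(g$trial$perception)$level
    n <- n + 1L
    if (lev == i) hits <- hits + 1L  # amplitudes 1.5/3.0/4.5 vs cut-points
  }
  expect_gte(hits / n, 0.95)
})
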