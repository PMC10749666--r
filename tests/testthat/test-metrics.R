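test_that("XCoM follows the pendulum scaling", {
  expect_equal(xcom(0.4, 0, 0.9), 0.4)
  expect_equal(xcom(0, 1, 0.9, g = 9.81), sqrt(0.9 / 9.81),
               tolerance = 1e-12)
  expect_equal(round(xcom(0, 1, 0.9), 4), 0.3029)
  # negating the velocity mirrors XCoM about the CoM
  expect_equal(xcom(0.2, 0.5, 0.9) - 0.2, 0.2 - xcom(0.2, -0.5, 0.9))
  expect_error(xcom(0, 1, -1), "positive")
})

test_that("margin of stability is the normalized toe-XCoM gap", {
  expect_equal(margin_of_stability(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(margin_of_stability(0.3, 0.4, 0.2), 0.5)
  expect_error(margin_of_stability(1, 1, 0), "positive")
})

test_that("inclination angle is the CoP-CoM angle from vertical", {
  expect_equal(inclination_angle(0.5, 1, 0.5), 0)
  expect_equal(inclination_angle(0.1, 1, 0), atan(0.1), tolerance = 1e-12)
  expect_equal(round(inclination_angle(0.1, 1, 0), 4), 0.0997)
  expect_equal(inclination_angle(-0.1, 1, 0), -inclination_angle(0.1, 1, 0))
  expect_error(inclination_angle(0, -1, 0), "positive")
})

test_that("whole-body angular momentum reduces to hand-computable cases", {
  bm <- build_body_model(quick_anthro())
  n <- nrow(bm)
  zero_kin <- list(pos_x = matrix(0, 1, n), pos_z = matrix(0, 1, n),
                   vel_x = matrix(0, 1, n), vel_z = matrix(0, 1, n),
                   orient = matrix(0, 1, n), angvel = matrix(0, 1, n))
  # one segment spinning about its own CoM at the body CoM: H = I w
  kin <- zero_kin
  kin$angvel[1, 2] <- 3
  expect_equal(whole_body_angular_momentum(kin, bm, normalize = FALSE),
               bm$inertia[2] * 3, tolerance = 1e-12)
  # common translation of every segment leaves H unchanged (zero here)
  kin2 <- zero_kin
  kin2$vel_x[] <- 1.4; kin2$vel_z[] <- -0.6
  expect_equal(whole_body_angular_momentum(kin2, bm, normalize = FALSE), 0,
               tolerance = 1e-12)
  # frame invariance on a random configuration
  kin3 <- random_segment_config(bm, seed = 2)
  h3 <- whole_body_angular_momentum(kin3, bm, normalize = FALSE)
  kin4 <- kin3
  kin4$vel_x <- kin3$vel_x + 2; kin4$vel_z <- kin3$vel_z - 1
  expect_equal(whole_body_angular_momentum(kin4, bm, normalize = FALSE), h3,
               tolerance = 1e-10)
})

test_that("two point masses give the hand-summed momentum", {
  # m = 1 kg at (+-0.5, 0) with velocities (0, +-1): H = 2 * 0.5 = 1
  bm <- build_body_model(quick_anthro())
  bm$mass[] <- 0; bm$inertia[] <- 0
  bm$mass[c(1, 2)] <- 1
  kin <- list(pos_x = matrix(c(0.5, -0.5, rep(0, 12)), 1),
              pos_z = matrix(0, 1, 14),
              vel_x = matrix(0, 1, 14),
              vel_z = matrix(c(1, -1, rep(0, 12)), 1),
              orient = matrix(0, 1, 14), angvel = matrix(0, 1, 14))
  expect_equal(whole_body_angular_momentum(kin, bm, normalize = FALSE), 1,
               tolerance = 1e-12)
})

test_that("analytic momenta match the particle-discretization oracle", {
  bm <- build_body_model(quick_anthro())
  for (s in 1:10) {
    kin <- random_segment_config(bm, seed = s)
    h <- whole_body_angular_momentum(kin, bm, normalize = FALSE)
    hp <- particle_wbam(kin, bm, n_p = 1000L)
    expect_lt(abs(h - hp) / max(abs(hp), 1e-9), 0.005)
  }
})

test_that("knee momentum obeys the rigid-rotation closed form", {
  bm <- build_body_model(quick_anthro())
  i <- match("shank_L", bm$segment)
  bm$mass[i] <- 3; bm$inertia[i] <- 0.05
  # shank rotating at w = 2 rad/s about a fixed knee, CoM 0.2 m below
  shank <- list(pos_x = 0.2, pos_z = 0, vel_x = 0, vel_z = 0.4, angvel = 2)
  thigh <- list(pos_x = 0, pos_z = 0, vel_x = 0, vel_z = 0, angvel = 0)
  knee <- list(x = 0, z = 0)
  h <- knee_momentum(thigh, shank, knee, bm, side = "L", normalize = FALSE)
  expect_equal(h, 0.05 * 2 + 0.2 * 3 * 0.4, tolerance = 1e-12)  # (I + m d^2) w
  # both segments static -> 0
  shank0 <- list(pos_x = 0.2, pos_z = -0.1, vel_x = 0, vel_z = 0, angvel = 0)
  expect_equal(knee_momentum(thigh, shank0, knee, bm, "L", normalize = FALSE), 0)
  expect_error(knee_momentum(thigh, shank, list(x = NULL), bm), "knee joint")
})

test_that("A-P CoP progression and V-CoM have their defining normalizations", {
  expect_equal(ap_cop_progression(rep(0.31, 50), 0.26), rep(0, 50))
  cop <- seq(0, 0.26, length.out = 60)
  p <- ap_cop_progression(cop + 5, 0.26)
  expect_equal(p[1], 0); expect_equal(p[60], 1)
  expect_true(all(diff(p) > 0))
  expect_true(all(is.na(ap_cop_progression(rep(NA_real_, 5), 0.26))))
  expect_error(ap_cop_progression(cop, 0), "positive")

  expect_equal(vcom_displacement(rep(0.93, 40), 1.8), rep(0, 40))
  z <- 0.9 + 0.02 * sin(seq(0, 2 * pi, length.out = 101))
  v <- vcom_displacement(z, 1.8)
  expect_equal(v[1], 0)
  expect_equal((max(v) - min(v)) / 2, 0.02 / 1.8, tolerance = 1e-6)
})

test_that("step length and width normalize heel separations by leg length", {
  sw <- step_length_width(list(x = 0, y = 0.1), list(x = 0.54, y = -0.14), 0.9)
  expect_equal(unname(sw["step_length"]), 0.6)
  expect_equal(unname(sw["step_width"]), 0.24 / 0.9)
  sw0 <- step_length_width(list(x = 1, y = 0.2), list(x = 1, y = 0.2), 0.9)
  expect_equal(unname(sw0), c(0, 0))
})

test_that("stance-referenced metrics are invariant to anterior lab-frame translation", {
  d <- 12.3
  com_x <- c(0.1, 0.2, 0.3); com_z <- c(1, 1.01, 1)
  cop <- c(0.05, 0.15, 0.3); toe <- c(0.4, 0.42, 0.45)
  vel <- c(1, 1.1, 1)
  xc <- xcom(com_x, vel, 0.9)
  expect_equal(margin_of_stability(xcom(com_x + d, vel, 0.9), toe + d),
               margin_of_stability(xc, toe))
  expect_equal(inclination_angle(com_x + d, com_z, cop + d),
               inclination_angle(com_x, com_z, cop))
  expect_equal(ap_cop_progression(cop + d, 0.26), ap_cop_progression(cop, 0.26))
  expect_equal(vcom_displacement(com_z, 1.8), vcom_displacement(com_z, 1.8))
})

test_that("generated normal gait reproduces the documented metric shapes", {
  zm <- zero_noise_metrics()
  m <- zm$m
  i <- 4L  # an interior stride
  mos <- m$traj$mos[i, ]
  ok <- which(is.finite(mos))
  # MoS starts positive (toe ahead of the XCoM) and decreases through stance
  expect_gt(mos[1], 0)
  expect_lt(mos[max(ok)], 0)
  expect_true(all(diff(mos[ok]) < 0.01))
  # A-P CoP progresses monotonically from the heel towards the toe
  cop <- m$traj$ap_cop[i, ]
  okc <- which(is.finite(cop))
  # starts at the heel (the first percent node sits a fraction of a sample
  # after the stance-onset reference)
  expect_lt(abs(cop[okc[1]]), 0.02)
  expect_gt(cop[max(okc)], 0.7)
  expect_true(all(diff(cop[okc]) > -1e-6))
  # knee momentum peaks near toe-off
  kh <- m$traj$knee_momentum[i, ]
  pk <- (0:100)[which.max(abs(kh))]
  expect_lt(abs(pk - m$meta$stance_end_pct[i]), 6)
  # commanded step length is recovered (leg-length normalized)
  expect_equal(m$meta$step_length[i],
               zm$truth$step_length / zm$anthro$leg_length,
               tolerance = 0.01)
})

test_that("disturbed strides show CoP braking and a lowered V-CoM", {
  an <- quick_anthro()
  cfg <- gait_config(an, noise_scale = 0)
  bm <- build_body_model(an)
  gd <- generate_trial(cfg, disturbance_spec("extension", "IDS", 3), seed = 1)
  md <- compute_stride_metrics(smooth_trial(synchronize(gd$trial)), bm)
  i <- which(md$meta$disturbed)
  copd <- md$traj$ap_cop[i, ]
  expect_lt(min(diff(copd[is.finite(copd)])), -0.01)  # backward movement
  zm <- zero_noise_metrics()
  w <- 10:60
  expect_lt(mean(md$traj$vcom[i, w] - zm$m$traj$vcom[4, w]), -5e-4)
})
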