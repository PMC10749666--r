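#' Synthetic gait generator configuration
#'
#' Defines the walking pattern one synthetic subject produces: cadence,
#' stance and double-support fractions, commanded step length and width,
#' per-joint Fourier coefficients of the sagittal joint trajectories, and
#' the noise model (smooth per-stride joint-trajectory deviations plus
#' white measurement noise). All randomness downstream is controlled by the
#' seed handed to [generate_trial()].
#'
#' @param anthro [anthropometrics()] of the simulated subject.
#' @param cadence strides per minute. The default (60/1.1, about 54.5)
#'   gives a 1.10 s stride — typical of self-paced walking and an integer
#'   number of samples at both native rates, so the noise-free gait is
#'   exactly periodic on the recording grids.
#' @param stance_fraction stance duration as a fraction of the gait cycle.
#' @param double_support_fraction duration of each double-support phase as
#'   a fraction of the cycle; must be smaller than the stance fraction.
#' @param step_length commanded step length (m).
#' @param step_width commanded step width (m).
#' @param n_strides prosthetic strides per walkway pass (default 7).
#' @param joints Fourier coefficients per joint (`thigh`, `knee`, `foot`),
#'   each `c(a0, c1..c4, s1..s4)`; defaults are a hand-tuned plausible
#'   sagittal gait.
#' @param noise_scale multiplies every noise SD; 0 gives a deterministic,
#'   perfectly periodic trial.
#' @param noise named list of noise SDs: `dev` (per-stride smooth joint
#'   deviation, rad), `trunk_dev` (postural sway, rad), `pelvis_z` (m),
#'   `pos`/`vel`/`angvel` (white measurement noise), `force` (N),
#'   `force_amp` (relative per-stride), `cop` (m), `width` (m, per-stride),
#'   `pulse_amp` (relative, log scale), `dip` (relative).
#' @return object of class `gait_config`.
#' @export
gait_config <- function(anthro,
                        cadence = 60 / 1.1,
                        stance_fraction = 0.62,
                        double_support_fraction = 0.12,
                        step_length = 0.55,
                        step_width = 0.24,
                        n_strides = 7L,
                        joints = default_joint_coefficients(),
                        noise_scale = 1,
                        noise = list(dev = 0.022, trunk_dev = 0.075,
                                     pelvis_z = 0.004, pos = 0.0015,
                                     vel = 0.008, angvel = 0.05,
                                     force = 3, force_amp = 0.04,
                                     cop = 0.002, width = 0.012,
                                     pulse_amp = 0.15, dip = 0.18)) {
  stopifnot(inherits(anthro, "anthropometrics"),
            stance_fraction > 0, stance_fraction < 1,
            double_support_fraction > 0,
            double_support_fraction < stance_fraction)
  structure(list(anthro = anthro, cadence = cadence,
                 stance_fraction = stance_fraction,
                 double_support_fraction = double_support_fraction,
                 step_length = step_length, step_width = step_width,
                 n_strides = as.integer(n_strides), joints = joints,
                 noise_scale = noise_scale, noise = noise),
            class = "gait_config")
}

#' Default sagittal joint-trajectory Fourier coefficients
#'
#' Four-harmonic series (`a0 + sum c_h cos(2 pi h phi) + s_h sin(2 pi h
#' phi)`) for the thigh angle (from vertical, positive forward), knee
#' flexion (positive, ~0.07 rad at heel strike, ~1.05 rad peak swing
#' flexion) and foot pitch (heel-to-toe axis from horizontal).
#'
#' @return named list of coefficient vectors.
#' @export
default_joint_coefficients <- function() {
  list(
    thigh = c(a0 = 0.1162, c1 = 0.3038, c2 = -0.0168, c3 = -0.0016,
              c4 = 0.0006, s1 = -0.0090, s2 = -0.0499, s3 = 0.0056,
              s4 = -0.0036),
    knee = c(a0 = 0.3731, c1 = -0.0463, c2 = -0.2440, c3 = -0.0148,
             c4 = -0.0005, s1 = -0.3505, s2 = 0.1237, s3 = 0.0588,
             s4 = -0.0118),
    foot = c(a0 = -0.0896, c1 = 0.2276, c2 = 0.0312, c3 = -0.0299,
             c4 = 0.0354, s1 = 0.1202, s2 = -0.1809, s3 = 0.0216,
             s4 = -0.0071))
}

#' Disturbance specification
#'
#' A 200 ms knee-level angular-velocity pulse. The knee-angle deviation is
#' `(A d / pi) sin^2(pi (t - t0) / d)`, i.e. an angular-velocity pulse
#' `A sin(2 pi (t - t0) / d)` of peak amplitude `A` (rad/s). Flexion pulses
#' are positive, extension negative; the amplitude grows strictly with the
#' intensity level.
#'
#' @param type "flexion" or "extension".
#' @param timing "IDS" (onset 3% of the cycle after prosthetic heel strike)
#'   or "SS" (onset at 25%).
#' @param intensity level 1, 2 or 3.
#' @param amplitudes peak angular-velocity amplitude (rad/s) per intensity
#'   level; strictly increasing.
#' @param duration pulse duration in seconds (protocol value 0.200).
#' @return object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(type = c("flexion", "extension"),
                             timing = c("IDS", "SS"),
                             intensity = 1L,
                             amplitudes = c(1.5, 3.0, 4.5),
                             duration = 0.200) {
  type <- match.arg(type); timing <- match.arg(timing)
  stopifnot(intensity %in% 1:3, length(amplitudes) == 3L,
            all(diff(amplitudes) > 0), all(amplitudes > 0),
            abs(duration - 0.200) < 1e-12)
  a <- amplitudes[intensity] * if (type == "flexion") 1 else -1
  structure(list(type = type, timing = timing, intensity = as.integer(intensity),
                 amplitude = a, duration = duration),
            class = "disturbance_spec")
}

#' Ordinal perception model configuration
#'
#' The reported level is a thresholded latent variable: `latent = coupling
#' * |realized pulse amplitude| + N(0, noise_sd)`, cut at three strictly
#' increasing thresholds into none/small/medium/large.
#'
#' @param coupling slope between the true injected knee-level deviation and
#'   the latent perception (default 1; 0 decouples perception from gait).
#' @param thresholds the three cut-points (strictly increasing).
#' @param noise_sd latent Gaussian noise SD.
#' @return object of class `perception_config`.
#' @export
perception_config <- function(coupling = 1,
                              thresholds = c(1.0, 2.4, 4.4),
                              noise_sd = 0.9) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0))
  structure(list(coupling = coupling, thresholds = thresholds,
                 noise_sd = noise_sd),
            class = "perception_config")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Fourier series value and d/dphi
fourier_eval <- function(coef, phi) {
  v <- rep(coef[["a0"]], length(phi))
  d <- numeric(length(phi))
  for (h in 1:4) {
    ch <- coef[[paste0("c", h)]]; sh <- coef[[paste0("s", h)]]
    w <- 2 * pi * h
    v <- v + ch * cos(w * phi) + sh * sin(w * phi)
    d <- d + w * (-ch * sin(w * phi) + sh * cos(w * phi))
  }
  list(v = v, d = d)
}

# smooth per-stride deviation: sin^2(pi u) (a + b sin 2 pi u + c cos 2 pi u),
# zero value and zero derivative at stride boundaries
stride_dev_eval <- function(phi_global, devmat) {
  k <- floor(phi_global)
  u <- phi_global - k
  n <- nrow(devmat)
  idx <- k + 1L
  ok <- idx >= 1L & idx <= n
  a <- b <- cc <- numeric(length(u))
  a[ok] <- devmat[idx[ok], 1L]
  b[ok] <- devmat[idx[ok], 2L]
  cc[ok] <- devmat[idx[ok], 3L]
  s2 <- sin(pi * u)^2
  inner <- a + b * sin(2 * pi * u) + cc * cos(2 * pi * u)
  dinner <- 2 * pi * (b * cos(2 * pi * u) - cc * sin(2 * pi * u))
  list(v = s2 * inner,
       d = pi * sin(2 * pi * u) * inner + s2 * dinner)
}

# disturbance knee-angle bump and its time derivative
pulse_eval <- function(t, onset, duration, amplitude) {
  u <- (t - onset) / duration
  inside <- u >= 0 & u <= 1
  v <- d <- numeric(length(t))
  v[inside] <- amplitude * duration / pi * sin(pi * u[inside])^2
  d[inside] <- amplitude * sin(2 * pi * u[inside])
  list(v = v, d = d)
}

# point helpers: lists with x, z, vx, vz
pt_chain_down <- function(prox, L, ang) {
  # ang: list(v = angle from vertical-down (positive forward), w = d/dt)
  list(x = prox$x + L * sin(ang$v), z = prox$z - L * cos(ang$v),
       vx = prox$vx + L * cos(ang$v) * ang$w,
       vz = prox$vz + L * sin(ang$v) * ang$w)
}
pt_chain_up <- function(prox, L, ang) {
  list(x = prox$x + L * sin(ang$v), z = prox$z + L * cos(ang$v),
       vx = prox$vx + L * cos(ang$v) * ang$w,
       vz = prox$vz - L * sin(ang$v) * ang$w)
}
pt_chain_horiz <- function(prox, L, ang) {
  list(x = prox$x + L * cos(ang$v), z = prox$z + L * sin(ang$v),
       vx = prox$vx - L * sin(ang$v) * ang$w,
       vz = prox$vz + L * cos(ang$v) * ang$w)
}
pt_along <- function(prox, dist, point) {
  # interpolate between prox and a distal point at fraction dist
  list(x = prox$x + dist * (point$x - prox$x),
       z = prox$z + dist * (point$z - prox$z),
       vx = prox$vx + dist * (point$vx - prox$vx),
       vz = prox$vz + dist * (point$vz - prox$vz))
}

#' Generate one synthetic walkway pass
#'
#' Builds a kinematically consistent 14-segment sagittal gait (joint-angle
#' Fourier series driven through forward kinematics, velocities by the
#' analytic chain rule), bilateral double-bump insole force with heel-to-toe
#' CoP progression, the prosthesis knee-angle channel, and optionally one
#' knee-level disturbance. The disturbance adds the angular-velocity pulse
#' of the [disturbance_spec()] to the prosthetic knee, a type- and
#' intensity-scaled late-stance stagnation dip to the prosthetic CoP
#' (mirroring the braking observed under real control faults), and a small
#' vertical-CoM dip. Ground truth (events, phase bounds, disturbed stride,
#' realized pulse, heel positions) is returned alongside.
#'
#' @param cfg [gait_config()].
#' @param disturbance [disturbance_spec()] or `NULL`.
#' @param seed integer seed controlling every random draw of this trial.
#' @param perception_cfg optional [perception_config()]; when present and
#'   the trial is disturbed, an ordinal perception label is drawn.
#' @param subject,trial identifiers.
#' @param fs_kin,fs_ins native sampling rates (Hz) of the kinematic and
#'   insole/knee streams.
#' @param sync_offset clock offset applied to the emitted kinematic stream.
#' @return list with `trial` (a [trial_recording()]) and `truth` (list:
#'   `events` ground-truth HS/TO per foot, `strides` phase-bound table,
#'   `disturbed_stride`, `onset`, `amplitude_realized`, `heel_x_pros`,
#'   `heel_x_contra`, `step_length`, `latent`).
#' @export
generate_trial <- function(cfg, disturbance = NULL, seed = 1L,
                           perception_cfg = NULL, subject = "S01",
                           trial = 1L, fs_kin = 60, fs_ins = 100,
                           sync_offset = 0) {
  stopifnot(inherits(cfg, "gait_config"))
  with_seed(seed, {
    an <- cfg$anthro
    T <- 60 / cfg$cadence
    n <- cfg$n_strides
    t0 <- 0.35 * T
    dur <- t0 + n * T + 0.45 * T
    ns <- cfg$noise_scale
    nz <- lapply(cfg$noise, function(s) s * ns)

    # --- per-stride random structure (indexed by prosthetic stride; the
    # contralateral leg gets its own set). +2 rows of margin for the
    # partial lead-in/out strides.
    ndev <- n + 2L
    draw_dev <- function(sd) matrix(stats::rnorm(3L * ndev, 0, sd), ndev, 3L)
    devs <- list(
      thigh_P = draw_dev(nz$dev), thigh_C = draw_dev(nz$dev),
      knee_P = draw_dev(nz$dev), knee_C = draw_dev(nz$dev),
      foot_P = draw_dev(nz$dev), foot_C = draw_dev(nz$dev),
      arm_L = draw_dev(nz$dev * 0.7), arm_R = draw_dev(nz$dev * 0.7),
      trunk = draw_dev(nz$trunk_dev),
      pelvis_z = draw_dev(nz$pelvis_z))
    force_amp <- stats::rnorm(2L * ndev, 0, nz$force_amp)
    width_jit <- stats::rnorm(2L * ndev, 0, nz$width)

    # --- disturbance placement
    pulse <- NULL; truth_dist <- NULL
    if (!is.null(disturbance)) {
      stopifnot(inherits(disturbance, "disturbance_spec"))
      k_d <- sample(2:(n - 1L), 1L)           # 1-based prosthetic stride
      phase_off <- if (disturbance$timing == "IDS") 0.03 else 0.25
      onset <- t0 + (k_d - 1L) * T + phase_off * T
      a_real <- disturbance$amplitude * exp(stats::rnorm(1L, 0, nz$pulse_amp))
      pulse <- list(onset = onset, duration = disturbance$duration,
                    amplitude = a_real)
      dip_base <- c(flexion = 0.10, extension = 0.13)[disturbance$type]
      dip_win <- if (disturbance$type == "flexion") c(0.50, 0.95) else c(0.42, 0.88)
      dip_amp <- dip_base * disturbance$intensity *
        exp(stats::rnorm(1L, 0, nz$dip))
      # contralateral hip recovery: users counter a perceived knee fault
      # with a variable-gain, ~100 ms delayed swing/hip adjustment of the
      # sound leg, which largely (and inconsistently) cancels the
      # disturbance in whole-body quantities
      rec_gain <- max(0, stats::rnorm(1L, 0.8, 0.35 * max(ns, 0.2)))
      recovery <- list(onset = onset + 0.08, duration = 0.20,
                       amplitude = -0.55 * a_real * rec_gain)
      truth_dist <- list(disturbed_stride = k_d, onset = onset,
                         amplitude_realized = a_real,
                         recovery = recovery,
                         dip = list(amplitude = dip_amp, window = dip_win))
    }

    # --- body evaluation at arbitrary times (shared by both native grids)
    eval_body <- function(t, with_pulse = TRUE) {
      phiP <- (t - t0) / T           # prosthetic-leg phase (stride = floor)
      phiC <- phiP + 0.5
      vbar <- 2 * cfg$step_length / T
      dphidt <- 1 / T

      ang <- function(base, phi, devmat) {
        f <- fourier_eval(cfg$joints[[base]], phi %% 1)
        dv <- stride_dev_eval(phi + 1, devmat)  # +1: lead-in occupies row 1
        list(v = f$v + dv$v, w = (f$d + dv$d) * dphidt)
      }
      th_P <- ang("thigh", phiP, devs$thigh_P)
      th_C <- ang("thigh", phiC, devs$thigh_C)
      kn_P <- ang("knee", phiP, devs$knee_P)
      kn_C <- ang("knee", phiC, devs$knee_C)
      ft_P <- ang("foot", phiP, devs$foot_P)
      ft_C <- ang("foot", phiC, devs$foot_C)
      if (!is.null(pulse) && with_pulse) {
        pv <- pulse_eval(t, pulse$onset, pulse$duration, pulse$amplitude)
        kn_P$v <- kn_P$v + pv$v
        kn_P$w <- kn_P$w + pv$d
        rc <- truth_dist$recovery
        rv <- pulse_eval(t, rc$onset, rc$duration, rc$amplitude)
        th_C$v <- th_C$v + rv$v
        th_C$w <- th_C$w + rv$d
      }

      # pelvis
      hip_h <- an$leg_length * 1.01
      pel_dev <- stride_dev_eval(phiP + 1, devs$pelvis_z)
      dip_v <- dip_d <- 0
      if (!is.null(pulse) && with_pulse) {
        dd <- pulse_eval(t, pulse$onset, 0.35,
                         -(0.006 + 0.002 * (if (is.null(disturbance)) 0 else disturbance$intensity)) * pi / 0.35)
        dip_v <- dd$v; dip_d <- dd$d
      }
      pelvis <- list(
        x = vbar * (t - t0) + 0.012 * sin(4 * pi * phiP + 2.0),
        z = hip_h + 0.022 * cos(4 * pi * phiP - 0.35) + pel_dev$v + dip_v,
        vx = vbar + 0.012 * 4 * pi * dphidt * cos(4 * pi * phiP + 2.0),
        vz = -0.022 * 4 * pi * dphidt * sin(4 * pi * phiP - 0.35) +
          pel_dev$d * dphidt + dip_d)

      # trunk and head (up-chain; angle from vertical-up, positive forward)
      tr_f <- stride_dev_eval(phiP + 1, devs$trunk)
      tr <- list(v = 0.04 + 0.025 * sin(4 * pi * phiP + 0.5) + tr_f$v,
                 w = (0.025 * 4 * pi * cos(4 * pi * phiP + 0.5) + tr_f$d) * dphidt)
      hd <- list(v = 0.8 * tr$v, w = 0.8 * tr$w)

      # arms (down-chain from the shoulder), anti-phase with ipsilateral leg
      arm <- function(phi, devmat) {
        dv <- stride_dev_eval(phi + 1, devmat)
        list(v = -0.13 * cos(2 * pi * phi) - 0.02 + dv$v,
             w = (0.13 * 2 * pi * sin(2 * pi * phi) + dv$d) * dphidt)
      }
      side_P <- if (an$affected_side == "left") "L" else "R"
      phi_of <- function(s) if (s == side_P) phiP else phiC
      dev_arm <- function(s) devs[[paste0("arm_", s)]]
      ua_L <- arm(phi_of("L"), dev_arm("L"))
      ua_R <- arm(phi_of("R"), dev_arm("R"))
      elb <- function(ua, phi)
        list(v = ua$v + 0.45 - 0.10 * cos(2 * pi * phi),
             w = ua$w + 0.10 * 2 * pi * sin(2 * pi * phi) * dphidt)
      fa_L <- elb(ua_L, phi_of("L")); fa_R <- elb(ua_R, phi_of("R"))

      # model lengths / fractions
      model <- body_model_cache(an)
      Lof <- function(seg) model$length[match(seg, model$segment)]
      cof <- function(seg) model$com_fraction[match(seg, model$segment)]

      shoulder <- pt_chain_up(pelvis, Lof("trunk"), tr)
      head_top <- pt_chain_up(shoulder, Lof("head_neck"), hd)

      legs <- function(th, kn, ft) {
        sh <- list(v = th$v - kn$v, w = th$w - kn$w)
        knee_j <- pt_chain_down(pelvis, Lof("thigh_L"), th)
        ankle <- pt_chain_down(knee_j, Lof("shank_L"), sh)
        toe <- pt_chain_horiz(ankle, Lof("foot_L"), ft)
        list(th = th, sh = sh, ft = ft, knee_j = knee_j, ankle = ankle, toe = toe)
      }
      leg_P <- legs(th_P, kn_P, ft_P)
      leg_C <- legs(th_C, kn_C, ft_C)
      leg_of <- function(s) if (s == side_P) leg_P else leg_C

      # assemble the 14 segments: CoM point, axis angle from +x, angvel
      segs <- list()
      segs$head_neck <- list(
        com = pt_along(shoulder, cof("head_neck"), head_top),
        alpha = pi / 2 - hd$v, w = -hd$w)
      segs$trunk <- list(com = pt_along(pelvis, 1 - cof("trunk"), shoulder),
                         alpha = pi / 2 - tr$v, w = -tr$w)
      # trunk CoM fraction is from the proximal (cranial) end in the table;
      # the chain runs caudal->cranial, hence 1 - fraction above.
      for (s in c("L", "R")) {
        ua <- if (s == "L") ua_L else ua_R
        fa <- if (s == "L") fa_L else fa_R
        elbow <- pt_chain_down(shoulder, Lof(paste0("upper_arm_", s)), ua)
        wrist <- pt_chain_down(elbow, Lof(paste0("forearm_", s)), fa)
        hand_d <- pt_chain_down(wrist, Lof(paste0("hand_", s)), fa)
        segs[[paste0("upper_arm_", s)]] <- list(
          com = pt_along(shoulder, cof(paste0("upper_arm_", s)), elbow),
          alpha = ua$v - pi / 2, w = ua$w)
        segs[[paste0("forearm_", s)]] <- list(
          com = pt_along(elbow, cof(paste0("forearm_", s)), wrist),
          alpha = fa$v - pi / 2, w = fa$w)
        segs[[paste0("hand_", s)]] <- list(
          com = pt_along(wrist, cof(paste0("hand_", s)), hand_d),
          alpha = fa$v - pi / 2, w = fa$w)
        lg <- leg_of(s)
        segs[[paste0("thigh_", s)]] <- list(
          com = pt_along(pelvis, cof(paste0("thigh_", s)), lg$knee_j),
          alpha = lg$th$v - pi / 2, w = lg$th$w)
        segs[[paste0("shank_", s)]] <- list(
          com = pt_along(lg$knee_j, cof(paste0("shank_", s)), lg$ankle),
          alpha = lg$sh$v - pi / 2, w = lg$sh$w)
        segs[[paste0("foot_", s)]] <- list(
          com = pt_along(lg$ankle, cof(paste0("foot_", s)), lg$toe),
          alpha = lg$ft$v, w = lg$ft$w)
      }
      list(segs = segs, pelvis = pelvis, legs = list(P = leg_P, C = leg_C),
           knee_P = kn_P, side_P = side_P)
    }

    # --- kinematic stream (native fs_kin)
    t_kin <- seq(0, dur, by = 1 / fs_kin)
    body <- eval_body(t_kin)
    nseg <- length(segment_names())
    nk <- length(t_kin)
    kin <- list(time = t_kin - sync_offset,
                pos_x = matrix(0, nk, nseg), pos_z = matrix(0, nk, nseg),
                vel_x = matrix(0, nk, nseg), vel_z = matrix(0, nk, nseg),
                orient = matrix(0, nk, nseg), angvel = matrix(0, nk, nseg),
                foot_y = matrix(0, nk, 2L))
    for (j in seq_len(nseg)) {
      sg <- body$segs[[segment_names()[j]]]
      kin$pos_x[, j] <- sg$com$x; kin$pos_z[, j] <- sg$com$z
      kin$vel_x[, j] <- sg$com$vx; kin$vel_z[, j] <- sg$com$vz
      kin$orient[, j] <- sg$alpha; kin$angvel[, j] <- sg$w
    }

    # lateral foot placement: per-stride targets, linear between
    # stance-midpoint knots
    side_P <- body$side_P
    ybase <- c(L = 0.5, R = -0.5) * cfg$step_width
    for (j in 1:2) {
      s <- c("L", "R")[j]
      off <- if (s == side_P) 0 else 0.5
      knots_t <- t0 + ((0:(n + 1L)) - 1L + off + cfg$stance_fraction / 2) * T
      knots_y <- ybase[s] + width_jit[seq_len(n + 2L) + (j - 1L) * ndev]
      kin$foot_y[, j] <- stats::approx(knots_t, knots_y, xout = t_kin,
                                       rule = 2)$y
    }

    # --- ground-truth events and phase bounds
    hs_P <- t0 + (0:n) * T
    to_P <- hs_P + cfg$stance_fraction * T
    hs_C <- t0 + ((0:(n + 1L)) - 0.5) * T
    to_C <- hs_C + cfg$stance_fraction * T
    keep_t <- function(x) x[x >= 0 & x <= dur]
    truth_events <- list(
      hs = stats::setNames(list(keep_t(if (side_P == "L") hs_P else hs_C),
                                keep_t(if (side_P == "L") hs_C else hs_P)),
                           c("L", "R")),
      to = stats::setNames(list(keep_t(if (side_P == "L") to_P else to_C),
                                keep_t(if (side_P == "L") to_C else to_P)),
                           c("L", "R")))
    ds <- cfg$double_support_fraction
    truth_strides <- data.frame(
      stride = 1:n, start = hs_P[1:n], end = hs_P[2:(n + 1L)],
      ids_end = hs_P[1:n] + ds * T,
      ss_end = hs_P[1:n] + 0.5 * T,
      stance_end = hs_P[1:n] + cfg$stance_fraction * T)

    # heel positions at the true heel-strike instants (noise-free)
    heel_at <- function(times, which_leg) {
      b <- eval_body(times)
      lg <- b$legs[[which_leg]]
      lg$ankle$x
    }
    heel_x_P <- heel_at(hs_P, "P")
    heel_x_C <- heel_at(hs_C[hs_C > 0 & hs_C < dur], "C")

    # --- insole stream (native fs_ins)
    t_ins <- seq(0, dur, by = 1 / fs_ins)
    W <- an$mass * 9.81
    force <- matrix(0, length(t_ins), 2L)
    cop <- matrix(NA_real_, length(t_ins), 2L)
    for (j in 1:2) {
      s <- c("L", "R")[j]
      off <- if (s == side_P) 0 else 0.5
      phi <- (t_ins - t0) / T - off
      k <- floor(phi)
      u <- (phi - k) / cfg$stance_fraction       # stance-phase coordinate
      in_st <- u >= 0 & u < 1
      e <- pmin(1, u / 0.04, (1 - u) / 0.04)
      e[!in_st] <- 0
      bump <- 1 + 0.12 * (-cos(4 * pi * u))
      amp <- 1 + force_amp[pmax(pmin(k + 2L, ndev), 1L) + (j - 1L) * ndev]
      f <- W * e * bump * amp
      f[!in_st] <- 0
      f <- f + stats::rnorm(length(f), 0, nz$force)
      force[, j] <- pmax(f, 0)

      # CoP: anchored at the stance's heel position, heel-to-toe progression
      hs_times <- t0 + (k + off) * T
      b_anch <- eval_body(unique(hs_times[in_st]))
      anchors <- stats::setNames(
        (if (s == side_P) b_anch$legs$P else b_anch$legs$C)$ankle$x,
        as.character(unique(hs_times[in_st])))
      anchor_x <- anchors[as.character(hs_times)]
      prog <- u - 0.12 * sin(2 * pi * u) / (2 * pi)
      cop_x <- anchor_x + an$foot_length * (0.05 + 0.85 * prog)
      if (!is.null(pulse) && s == side_P) {
        dw <- truth_dist$dip$window
        in_dip <- in_st & u >= dw[1] & u <= dw[2] &
          abs(t_ins - pulse$onset) < 2 * T & t_ins > pulse$onset
        ud <- (u - dw[1]) / (dw[2] - dw[1])
        cop_x[in_dip] <- cop_x[in_dip] -
          truth_dist$dip$amplitude * an$foot_length * sin(pi * ud[in_dip])^2
      }
      cop_x <- cop_x + stats::rnorm(length(cop_x), 0, nz$cop)
      cop_x[!in_st] <- NA_real_
      cop[, j] <- cop_x
    }

    # --- knee-angle channel (prosthetic knee, includes the pulse)
    bk <- eval_body(t_ins)
    knee_angle <- bk$knee_P$v + stats::rnorm(length(t_ins), 0, 0.5 * nz$angvel / 10)

    # white measurement noise on the kinematic channels
    if (ns > 0) {
      kin$pos_x <- kin$pos_x + stats::rnorm(length(kin$pos_x), 0, nz$pos)
      kin$pos_z <- kin$pos_z + stats::rnorm(length(kin$pos_z), 0, nz$pos)
      kin$vel_x <- kin$vel_x + stats::rnorm(length(kin$vel_x), 0, nz$vel)
      kin$vel_z <- kin$vel_z + stats::rnorm(length(kin$vel_z), 0, nz$vel)
      kin$angvel <- kin$angvel + stats::rnorm(length(kin$angvel), 0, nz$angvel)
    }

    # --- perception label
    perception <- NULL; latent <- NA_real_
    if (!is.null(disturbance)) {
      if (!is.null(perception_cfg)) {
        latent <- perception_cfg$coupling * abs(pulse$amplitude) +
          stats::rnorm(1L, 0, perception_cfg$noise_sd)
        lev <- findInterval(latent, perception_cfg$thresholds)
        perception <- c("none", "small", "medium", "large")[lev + 1L]
      }
    }

    dist_log <- if (is.null(disturbance)) NULL else
      list(onset = pulse$onset, duration = disturbance$duration,
           type = disturbance$type, timing = disturbance$timing,
           intensity = disturbance$intensity)

    tr <- trial_recording(
      kin = kin,
      insole = list(time = t_ins, force = force, cop_x = cop),
      knee = list(time = t_ins, angle = knee_angle),
      anthro = an, disturbance = dist_log, perception = perception,
      sync_offset = sync_offset, subject = subject, trial = trial)

    truth <- c(list(events = truth_events, strides = truth_strides,
                    heel_x_pros = heel_x_P, heel_x_contra = heel_x_C,
                    step_length = cfg$step_length, stride_period = T,
                    latent = latent),
               truth_dist)
    list(trial = tr, truth = truth)
  })
}

# body models are pure functions of the anthropometrics; memoize per subject
.bm_cache <- new.env(parent = emptyenv())
body_model_cache <- function(anthro) {
  key <- paste(anthro$height, anthro$mass, anthro$leg_length,
               anthro$foot_length, anthro$affected_side, sep = "|")
  if (is.null(.bm_cache[[key]]))
    .bm_cache[[key]] <- build_body_model(anthro)
  .bm_cache[[key]]
}

#' Generate a synthetic cohort schedule
#'
#' Lays out, per subject, a randomized schedule of disturbed walkway passes
#' covering the full condition grid (2 types x 2 timings x 3 intensities),
#' with one seed per trial so any pass can be re-materialized on demand by
#' [realize_trial()] without holding the whole cohort in memory.
#'
#' @param n_subjects number of subjects (default 7). The default
#'   anthropometrics cycle through the packaged demographic table.
#' @param n_trials disturbed passes per subject (default 168, i.e. 28
#'   repeats of the six type-by-intensity conditions); must be a multiple
#'   of 12 so every condition appears equally often.
#' @param seed master seed; per-trial seeds are drawn from it.
#' @param coupling latent perception coupling (see [perception_config()]).
#' @param noise_scale generator noise multiplier.
#' @param anthros optional list of [anthropometrics()] per subject.
#' @param ... further arguments passed to [gait_config()].
#' @return object of class `gait_cohort`: list with `subjects` (each:
#'   `subject`, `anthro`, `cfg`, `schedule` data.frame with `trial`,
#'   `type`, `timing`, `intensity`, `seed`) and `perception_cfg`.
#' @export
generate_cohort <- function(n_subjects = 7L, n_trials = 168L, seed = 1L,
                            coupling = 1, noise_scale = 1, anthros = NULL,
                            ...) {
  stopifnot(n_trials %% 12L == 0L)
  if (is.null(anthros)) {
    demo <- utils::read.csv(system.file("extdata", "subjects.csv",
                                        package = "gaitstab"))
    anthros <- lapply(seq_len(n_subjects), function(i) {
      d <- demo[((i - 1L) %% nrow(demo)) + 1L, ]
      anthropometrics(d$height_m, d$mass_kg, affected_side = d$affected_side)
    })
  }
  stopifnot(length(anthros) == n_subjects)
  pc <- perception_config(coupling = coupling)
  with_seed(seed, {
    subjects <- lapply(seq_len(n_subjects), function(i) {
      grid <- expand.grid(type = c("flexion", "extension"),
                          timing = c("IDS", "SS"),
                          intensity = 1:3, stringsAsFactors = FALSE)
      sched <- grid[rep(seq_len(nrow(grid)), n_trials / 12L), ]
      sched <- sched[sample.int(nrow(sched)), ]
      sched$trial <- seq_len(nrow(sched))
      sched$seed <- sample.int(.Machine$integer.max, nrow(sched))
      rownames(sched) <- NULL
      list(subject = sprintf("S%02d", i), anthro = anthros[[i]],
           cfg = gait_config(anthros[[i]], noise_scale = noise_scale, ...),
           schedule = sched[, c("trial", "type", "timing", "intensity", "seed")])
    })
    structure(list(subjects = subjects, perception_cfg = pc, seed = seed),
              class = "gait_cohort")
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects x %d disturbed trials (coupling %.2f)\n",
              length(x$subjects), nrow(x$subjects[[1]]$schedule),
              x$perception_cfg$coupling))
  invisible(x)
}

#' Materialize one scheduled trial of a cohort
#'
#' @param cohort a [generate_cohort()] object.
#' @param subject_idx subject index.
#' @param trial_idx trial index within that subject's schedule.
#' @return a [generate_trial()] result (`trial` + `truth`).
#' @export
realize_trial <- function(cohort, subject_idx, trial_idx) {
  su <- cohort$subjects[[subject_idx]]
  row <- su$schedule[trial_idx, ]
  d <- disturbance_spec(row$type, row$timing, row$intensity)
  generate_trial(su$cfg, d, seed = row$seed,
                 perception_cfg = cohort$perception_cfg,
                 subject = su$subject, trial = row$trial)
}
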