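# shared fixtures and independent oracles

quick_anthro <- function(height = 1.75, mass = 80, side = "left")
  anthropometrics(height, mass, affected_side = side)

# random rigid-segment configurations for the momentum oracles: positions,
# orientations, velocities and angular velocities drawn freely (Eq. 2/3 do
# not require chain consistency)
random_segment_config <- function(model, seed) {
  set.seed(seed)
  n <- nrow(model)
  list(pos_x = matrix(stats::rnorm(n, 0, 0.5), 1L),
       pos_z = matrix(stats::rnorm(n, 1, 0.3), 1L),
       vel_x = matrix(stats::rnorm(n, 0, 1), 1L),
       vel_z = matrix(stats::rnorm(n, 0, 1), 1L),
       orient = matrix(stats::runif(n, -pi, pi), 1L),
       angvel = matrix(stats::rnorm(n, 0, 3), 1L))
}

# independent particle oracle: each segment is replaced by n_p point masses
# uniformly spaced (midpoint grid) on an interval centred on the segment CoM
# with half-width sqrt(3) * radius of gyration along the segment axis, which
# reproduces (m, CoM, I) up to a 1/n_p^2 discretisation error. Particle
# velocities follow rigid-body motion; the momentum is the raw particle sum.
particle_wbam <- function(kin, model, n_p = 1000L) {
  m_tot <- sum(model$mass)
  comx <- sum(kin$pos_x[1, ] * model$mass) / m_tot
  comz <- sum(kin$pos_z[1, ] * model$mass) / m_tot
  comvx <- sum(kin$vel_x[1, ] * model$mass) / m_tot
  comvz <- sum(kin$vel_z[1, ] * model$mass) / m_tot
  H <- 0
  for (i in seq_len(nrow(model))) {
    k <- sqrt(model$inertia[i] / model$mass[i])   # radius of gyration
    a <- sqrt(3) * k
    s <- a * (2 * seq_len(n_p) - n_p - 1) / n_p   # midpoint offsets
    ux <- cos(kin$orient[1, i]); uz <- sin(kin$orient[1, i])
    px <- kin$pos_x[1, i] + s * ux
    pz <- kin$pos_z[1, i] + s * uz
    w <- kin$angvel[1, i]
    vx <- kin$vel_x[1, i] - w * (pz - kin$pos_z[1, i])
    vz <- kin$vel_z[1, i] + w * (px - kin$pos_x[1, i])
    mp <- model$mass[i] / n_p
    H <- H + sum(mp * ((px - comx) * (vz - comvz) - (pz - comz) * (vx - comvx)))
  }
  H
}

particle_knee_momentum <- function(thigh, shank, knee, model, side = "L",
                                   n_p = 1000L) {
  H <- 0
  for (seg in list(list(k = thigh, row = paste0("thigh_", side)),
                   list(k = shank, row = paste0("shank_", side)))) {
    i <- match(seg$row, model$segment)
    k <- sqrt(model$inertia[i] / model$mass[i])
    a <- sqrt(3) * k
    s <- a * (2 * seq_len(n_p) - n_p - 1) / n_p
    # axis direction: use the stored orientation if present, else x-axis
    th <- if (!is.null(seg$k$orient)) seg$k$orient else 0
    px <- seg$k$pos_x + s * cos(th)
    pz <- seg$k$pos_z + s * sin(th)
    w <- seg$k$angvel
    vx <- seg$k$vel_x - w * (pz - seg$k$pos_z)
    vz <- seg$k$vel_z + w * (px - seg$k$pos_x)
    mp <- model$mass[i] / n_p
    H <- H + sum(mp * ((px - knee$x) * vz - (pz - knee$z) * vx))
  }
  H
}

# brute-force Kendall tau-b over all pairs, with tie correction
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# a small zero-noise processed trial, cached per session
zero_noise_metrics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      an <- quick_anthro()
      g <- generate_trial(gait_config(an, noise_scale = 0), NULL, seed = 1)
      tr <- smooth_trial(synchronize(g$trial))
      cache <<- list(m = compute_stride_metrics(tr, build_body_model(an)),
                     truth = g$truth, anthro = an)
    }
    cache
  }
})
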