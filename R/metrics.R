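#' Extrapolated centre of mass (XCoM)
#'
#' Hof's inverted-pendulum extrapolation: the CoM position advanced by its
#' anterior velocity scaled with the pendulum time constant,
#' `XCoM = CoM + velCoM * sqrt(l / g)`.
#'
#' @param com_x anterior CoM position (m).
#' @param vel_x anterior CoM velocity (m/s).
#' @param leg_length pendulum length `l` (m).
#' @param g gravitational acceleration (default 9.81 m/s^2).
#' @return XCoM trajectory (m).
#' @export
xcom <- function(com_x, vel_x, leg_length, g = 9.81) {
  if (!is.numeric(leg_length) || leg_length <= 0)
    stop("leg_length must be positive", call. = FALSE)
  com_x + vel_x * sqrt(leg_length / g)
}

#' Margin of stability
#'
#' Signed anterior distance from the XCoM to the base-of-support boundary
#' (the prosthetic toe), optionally divided by the excursion (max - min) of
#' the subject's mean normal profile. Positive while the toe is ahead of
#' the XCoM.
#'
#' @param xcom_x XCoM trajectory (m), stance window.
#' @param toe_x prosthetic toe trajectory (m), same grid.
#' @param normal_excursion excursion of the mean normal MoS profile; the
#'   default 1 leaves the metric in metres (the pipeline normalizes at the
#'   template stage).
#' @return MoS trajectory.
#' @export
margin_of_stability <- function(xcom_x, toe_x, normal_excursion = 1) {
  if (!is.numeric(normal_excursion) || normal_excursion <= 0)
    stop("normal_excursion must be positive", call. = FALSE)
  (toe_x - xcom_x) / normal_excursion
}

#' Sagittal inclination angle
#'
#' Angle between the vertical through the CoP and the CoP-to-CoM line,
#' `atan2(CoM_x - CoP_x, CoM_z)`. Positive when the CoM is ahead of the CoP.
#'
#' @param com_x,com_z CoM anterior position and height (m).
#' @param cop_x prosthetic-foot CoP anterior position (m), NA when unloaded.
#' @param normal_excursion as in [margin_of_stability()].
#' @return inclination-angle trajectory (rad before normalization).
#' @export
inclination_angle <- function(com_x, com_z, cop_x, normal_excursion = 1) {
  if (any(com_z <= 0, na.rm = TRUE))
    stop("CoM height must be positive", call. = FALSE)
  atan2(com_x - cop_x, com_z) / normal_excursion
}

#' Whole-body angular momentum about the body CoM
#'
#' Sagittal-plane scalar of `sum_i [ I_i w_i + r_i x m_i (v_i - V_CoM) ]`
#' over the 14 segments, with `r_i` the segment-CoM offset from the body
#' CoM. The scalar is the out-of-plane component `dx * vz - dz * vx`
#' (positive = counter-clockwise with x anterior, z up). Normalized by
#' body mass times height.
#'
#' @param kin `kin` element of a synchronized trial (or any list with
#'   matching matrices).
#' @param model [build_body_model()] model.
#' @param com whole-body CoM as from [whole_body_com()]; computed if `NULL`.
#' @param normalize divide by mass*height (default TRUE).
#' @return momentum trajectory (kg m^2/s, or dimensionless/(m s^-1) scale
#'   when normalized).
#' @export
whole_body_angular_momentum <- function(kin, model, com = NULL,
                                        normalize = TRUE) {
  if (!identical(model$segment, segment_names()))
    stop("model segments do not match the kinematic segment set", call. = FALSE)
  if (is.null(com)) com <- whole_body_com(kin, model)
  m <- model$mass
  dx <- sweep(kin$pos_x, 1L, com$x)
  dz <- sweep(kin$pos_z, 1L, com$z)
  rvx <- sweep(kin$vel_x, 1L, com$vx)
  rvz <- sweep(kin$vel_z, 1L, com$vz)
  spin <- drop(kin$angvel %*% model$inertia)
  orbit <- drop((dx * rvz - dz * rvx) %*% m)
  h <- spin + orbit
  if (normalize) {
    anthro <- attr(model, "anthro")
    h <- h / (anthro$mass * anthro$height)
  }
  h
}

#' Knee momentum: thigh + shank angular momentum about the knee joint
#'
#' Sagittal-plane scalar of `[I w + r_knee->CoM x m v]` summed over the
#' residual thigh and the prosthetic shank, with absolute segment-CoM
#' velocities `v`, about the (moving) prosthetic knee-joint position.
#' Normalized by body mass times height.
#'
#' @param thigh,shank lists with `pos_x`, `pos_z`, `vel_x`, `vel_z`,
#'   `angvel` vectors for the two segments.
#' @param knee list with `x`, `z`: knee-joint position per sample.
#' @param model body model (masses/inertias for `thigh_*`, `shank_*` rows
#'   of the prosthetic side).
#' @param side prosthetic side `"L"` or `"R"`.
#' @param normalize divide by mass*height (default TRUE).
#' @return knee-momentum trajectory.
#' @export
knee_momentum <- function(thigh, shank, knee, model, side = "L",
                          normalize = TRUE) {
  if (is.null(knee$x) || is.null(knee$z))
    stop("knee joint position is required", call. = FALSE)
  h <- 0
  for (seg in list(list(k = thigh, row = paste0("thigh_", side)),
                   list(k = shank, row = paste0("shank_", side)))) {
    i <- match(seg$row, model$segment)
    dx <- seg$k$pos_x - knee$x
    dz <- seg$k$pos_z - knee$z
    h <- h + model$inertia[i] * seg$k$angvel +
      model$mass[i] * (dx * seg$k$vel_z - dz * seg$k$vel_x)
  }
  if (normalize) {
    anthro <- attr(model, "anthro")
    h <- h / (anthro$mass * anthro$height)
  }
  h
}

#' Anterior-posterior CoP progression
#'
#' Anterior displacement of the prosthetic-foot CoP from its stance-onset
#' value, divided by foot length: the heel-to-toe progression, 0 at heel
#' strike and ~1 when the CoP reaches the toe.
#'
#' @param cop_x prosthetic CoP over the stance window (m; NA where masked).
#' @param foot_length foot length (m).
#' @return normalized progression trajectory.
#' @export
ap_cop_progression <- function(cop_x, foot_length) {
  if (!is.numeric(foot_length) || foot_length <= 0)
    stop("foot_length must be positive", call. = FALSE)
  first <- which(!is.na(cop_x))[1L]
  if (is.na(first)) return(rep(NA_real_, length(cop_x)))
  (cop_x - cop_x[first]) / foot_length
}

#' Vertical CoM displacement
#'
#' CoM height relative to its cycle-onset value, divided by standing height.
#'
#' @param com_z CoM height over the gait cycle (m).
#' @param height standing height (m).
#' @return normalized V-CoM trajectory.
#' @export
vcom_displacement <- function(com_z, height) {
  (com_z - com_z[1L]) / height
}

#' Step length and step width of a prosthetic-initiated step
#'
#' Anterior (length) and mediolateral (width) separation of the prosthetic
#' heel at its heel strike and the contralateral heel at the following heel
#' strike, both normalized to leg length.
#'
#' @param pros_heel list with `x`, `y`: prosthetic heel position at its HS.
#' @param contra_heel list with `x`, `y`: contralateral heel at the next HS.
#' @param leg_length leg length (m).
#' @return named numeric vector `c(step_length=, step_width=)`.
#' @export
step_length_width <- function(pros_heel, contra_heel, leg_length) {
  c(step_length = (contra_heel$x - pros_heel$x) / leg_length,
    step_width = abs(contra_heel$y - pros_heel$y) / leg_length)
}

metric_names_trajectory <- function()
  c("mos", "inclination", "wbam", "knee_momentum", "ap_cop", "vcom")

metric_names_scalar <- function() c("step_length", "step_width")

#' All metric names computed by the pipeline
#' @return character vector of the eight metric names.
#' @export
metric_names <- function() c(metric_names_scalar(), metric_names_trajectory())

# segment endpoint helper: distal/proximal point from CoM, orientation and
# the model's length/CoM fraction. orient is the proximal->distal axis angle
# from the +x (anterior) axis.
segment_point <- function(kin, model, segment, what = c("distal", "proximal")) {
  what <- match.arg(what)
  i <- match(segment, model$segment)
  j <- match(segment, segment_names())
  f <- if (what == "distal") (1 - model$com_fraction[i]) else -model$com_fraction[i]
  ux <- cos(kin$orient[, j]); uz <- sin(kin$orient[, j])
  list(x = kin$pos_x[, j] + f * model$length[i] * ux,
       z = kin$pos_z[, j] + f * model$length[i] * uz,
       vx = kin$vel_x[, j] + f * model$length[i] * (-uz) * kin$angvel[, j],
       vz = kin$vel_z[, j] + f * model$length[i] * ux * kin$angvel[, j])
}

segment_channels <- function(kin, segment) {
  j <- match(segment, segment_names())
  list(pos_x = kin$pos_x[, j], pos_z = kin$pos_z[, j],
       vel_x = kin$vel_x[, j], vel_z = kin$vel_z[, j],
       angvel = kin$angvel[, j])
}

#' Compute all per-stride metric trajectories and scalars for one trial
#'
#' Runs event detection on the raw insole force, segments prosthetic
#' strides, and evaluates the eight metrics. Trajectory metrics are
#' time-normalized to the percent-gait-cycle grid; stance-window metrics
#' (MoS, inclination angle, A-P CoP) are NA beyond the stride's stance end.
#' MoS and inclination angle are left un-normalized here; the template
#' stage divides them by the normal-profile excursion.
#'
#' @param trial synchronized (and usually smoothed) [trial_recording()].
#' @param model [build_body_model()] for the trial's subject.
#' @param n_points percent-grid size (default 101).
#' @param threshold_n,debounce_s event-detection settings.
#' @param g gravitational acceleration.
#' @return list with `meta` (one row per stride: identifiers, phase bounds
#'   in percent, disturbance condition, perception, step length/width) and
#'   `traj` (named list of stride-by-percent matrices, one per trajectory
#'   metric).
#' @export
compute_stride_metrics <- function(trial, model, n_points = 101L,
                                   threshold_n = 30, debounce_s = 0.05,
                                   g = 9.81) {
  anthro <- trial$anthro
  side <- if (anthro$affected_side == "left") "L" else "R"
  other <- setdiff(c("L", "R"), side)
  side_col <- match(side, c("L", "R"))
  other_col <- match(other, c("L", "R"))

  ev <- detect_events(trial$insole$time, trial$insole$force,
                      threshold_n, debounce_s)
  strides <- segment_strides(ev, side)
  strides <- mark_disturbed(strides, trial$disturbance)

  kin <- trial$kin
  tt <- kin$time
  com <- whole_body_com(kin, model)
  xc <- xcom(com$x, com$vx, anthro$leg_length, g)
  toe <- segment_point(kin, model, paste0("foot_", side), "distal")
  knee_pos <- segment_point(kin, model, paste0("thigh_", side), "distal")
  mos_raw <- margin_of_stability(xc, toe$x)
  cop_pros <- trial$insole$cop_x[, side_col]
  incl_raw <- inclination_angle(com$x, com$z, cop_pros)
  wbam <- whole_body_angular_momentum(kin, model, com)
  kneeH <- knee_momentum(segment_channels(kin, paste0("thigh_", side)),
                         segment_channels(kin, paste0("shank_", side)),
                         knee_pos, model, side)

  heel_pros <- segment_point(kin, model, paste0("foot_", side), "proximal")
  heel_contra <- segment_point(kin, model, paste0("foot_", other), "proximal")

  nst <- nrow(strides)
  traj <- lapply(metric_names_trajectory(), function(m)
    matrix(NA_real_, nst, n_points))
  names(traj) <- metric_names_trajectory()
  pct <- seq(0, 100, length.out = n_points)

  meta <- strides
  meta$subject <- anthro_subject(trial)
  meta$trial <- trial$trial
  meta$stance_end_pct <- with(strides, 100 * (stance_end - start) / (end - start))
  meta$onset_pct <- NA_real_
  meta$step_length <- NA_real_
  meta$step_width <- NA_real_

  for (i in seq_len(nst)) {
    if (!strides$usable[i]) next
    s <- strides$start[i]; e <- strides$end[i]
    sel <- tt >= s - 0.02 & tt <= e + 0.02
    tn <- function(v) time_normalize(tt[sel], v[sel], s, e, n_points)
    stance_pct <- meta$stance_end_pct[i]

    m_mos <- tn(mos_raw); m_mos[pct > stance_pct] <- NA_real_
    m_incl <- tn(incl_raw); m_incl[pct > stance_pct] <- NA_real_
    copw <- ap_cop_progression(
      ifelse(tt >= s & tt <= strides$stance_end[i], cop_pros, NA_real_),
      anthro$foot_length)
    m_cop <- tn(copw); m_cop[pct > stance_pct] <- NA_real_
    # V-CoM referenced to cycle onset: subtract CoM height at stride start
    z0 <- stats::approx(tt, com$z, xout = s)$y
    m_vcom <- tn((com$z - z0) / anthro$height)

    traj$mos[i, ] <- m_mos
    traj$inclination[i, ] <- m_incl
    traj$ap_cop[i, ] <- m_cop
    traj$vcom[i, ] <- m_vcom
    traj$wbam[i, ] <- tn(wbam)
    traj$knee_momentum[i, ] <- tn(kneeH)

    # spatial scalars: prosthetic HS at stride start, contralateral HS at ss_end
    hp <- list(x = stats::approx(tt, heel_pros$x, xout = s)$y,
               y = stats::approx(tt, kin$foot_y[, side_col], xout = s)$y)
    hc <- list(x = stats::approx(tt, heel_contra$x, xout = strides$ss_end[i])$y,
               y = stats::approx(tt, kin$foot_y[, other_col],
                                 xout = strides$ss_end[i])$y)
    sw <- step_length_width(hp, hc, anthro$leg_length)
    meta$step_length[i] <- sw["step_length"]
    meta$step_width[i] <- sw["step_width"]

    if (strides$disturbed[i] && !is.null(trial$disturbance))
      meta$onset_pct[i] <- 100 * (trial$disturbance$onset - s) / (e - s)
  }

  meta$type <- if (is.null(trial$disturbance)) NA_character_ else trial$disturbance$type
  meta$timing <- if (is.null(trial$disturbance)) NA_character_ else trial$disturbance$timing
  meta$intensity <- if (is.null(trial$disturbance)) NA_integer_ else trial$disturbance$intensity
  meta$perception <- if (is.null(trial$perception)) NA_character_ else trial$perception

  list(meta = meta, traj = traj)
}

anthro_subject <- function(trial) {
  if (!is.null(trial$subject)) trial$subject else "S01"
}
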