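#' Construct a trial recording
#'
#' Bundles the three native sensor streams of one walkway pass: 14-segment
#' sagittal kinematics (native 60 Hz), bilateral insole vertical force and
#' anterior CoP (native 100 Hz), and the prosthesis knee angle (100 Hz),
#' plus the disturbance log and the user's ordinal perception report.
#'
#' @param kin list with `time` (s) and n-by-14 matrices `pos_x`, `pos_z`
#'   (segment CoM, m), `vel_x`, `vel_z` (m/s), `orient` (rad, unwrapped),
#'   `angvel` (rad/s), and an n-by-2 `foot_y` (lateral foot coordinate, m,
#'   columns L/R). Columns follow [segment_names()].
#' @param insole list with `time` and n-by-2 matrices `force` (N, >= 0) and
#'   `cop_x` (anterior CoP, m; NA where the foot is unloaded), columns L/R.
#' @param knee list with `time` and `angle` (rad).
#' @param anthro [anthropometrics()].
#' @param disturbance `NULL`, or list with `onset` (s), `duration` (s,
#'   0.200), `type` ("flexion"/"extension"), `timing` ("IDS"/"SS"),
#'   `intensity` (1:3).
#' @param perception `NULL` or one of "none","small","medium","large".
#' @param sync_offset clock offset (s) of the kinematic stream: true time =
#'   `kin$time + sync_offset`.
#' @param subject,trial identifiers carried through the pipeline.
#' @return object of class `trial_recording`.
#' @export
trial_recording <- function(kin, insole, knee, anthro, disturbance = NULL,
                            perception = NULL, sync_offset = 0,
                            subject = "S01", trial = 1L) {
  stopifnot(inherits(anthro, "anthropometrics"))
  nseg <- length(segment_names())
  for (nm in c("pos_x", "pos_z", "vel_x", "vel_z", "orient", "angvel")) {
    m <- kin[[nm]]
    if (is.null(m) || ncol(m) != nseg || nrow(m) != length(kin$time))
      stop("kin$", nm, " must be a length(time) x 14 matrix", call. = FALSE)
    if (!all(is.finite(m))) stop("non-finite values in kin$", nm, call. = FALSE)
  }
  if (any(insole$force < 0, na.rm = TRUE))
    stop("insole force must be non-negative", call. = FALSE)
  if (!is.null(disturbance)) {
    if (abs(disturbance$duration - 0.200) > 1e-9)
      stop("disturbance duration must be 0.200 s", call. = FALSE)
    span <- range(insole$time)
    if (disturbance$onset < span[1] || disturbance$onset > span[2])
      stop("disturbance onset outside the recording span", call. = FALSE)
    stopifnot(disturbance$type %in% c("flexion", "extension"),
              disturbance$timing %in% c("IDS", "SS"),
              disturbance$intensity %in% 1:3)
  }
  if (!is.null(perception))
    stopifnot(perception %in% c("none", "small", "medium", "large"))
  structure(
    list(kin = kin, insole = insole, knee = knee, anthro = anthro,
         disturbance = disturbance, perception = perception,
         sync_offset = sync_offset, subject = subject, trial = trial),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  d <- if (is.null(x$disturbance)) "none" else
    with(x$disturbance, sprintf("%s @ %s, intensity %d, onset %.2f s",
                                type, timing, intensity, onset))
  cat(sprintf("<trial_recording> %s trial %s: %.1f s kinematics @%.0f Hz, disturbance: %s, perception: %s\n",
              x$subject, x$trial, diff(range(x$kin$time)),
              1 / stats::median(diff(x$kin$time)), d,
              if (is.null(x$perception)) "absent" else x$perception))
  invisible(x)
}

#' Synchronize all streams of a trial onto one analysis grid
#'
#' Applies the kinematic stream's sync offset, intersects the recorded spans,
#' and resamples every channel onto a uniform grid at `target_fs` covering
#' the overlap (no extrapolation). Smooth kinematic and knee-angle channels
#' are spline-resampled; the insole force is linearly interpolated (its
#' edges are what define gait events and splines overshoot at steps); the
#' CoP is linearly interpolated across its loaded samples and re-masked
#' where the resampled force is below `cop_mask_n`.
#'
#' @param trial a [trial_recording()].
#' @param target_fs analysis rate in Hz (default 100, the insole rate).
#' @param cop_mask_n vertical-force validity threshold for CoP samples (N).
#' @return a `trial_recording` whose three streams share one time grid, with
#'   attribute `fs` set; `sync_offset` is consumed (set to 0).
#' @export
synchronize <- function(trial, target_fs = 100, cop_mask_n = 30) {
  kt <- trial$kin$time + trial$sync_offset
  t0 <- max(kt[1], trial$insole$time[1], trial$knee$time[1])
  t1 <- min(kt[length(kt)], max(trial$insole$time), max(trial$knee$time))
  if (t1 <= t0)
    stop("synchronize: streams do not overlap in time", call. = FALSE)
  grid <- seq(t0, t1, by = 1 / target_fs)

  kin <- trial$kin
  out_kin <- list(time = grid)
  for (nm in c("pos_x", "pos_z", "vel_x", "vel_z", "orient", "angvel", "foot_y"))
    out_kin[[nm]] <- resample_series(kt, kin[[nm]], grid)

  it <- trial$insole$time
  force <- apply(trial$insole$force, 2L, function(col)
    stats::approx(it, col, xout = grid, rule = 1)$y)
  force <- pmax(force, 0)
  cop <- sapply(seq_len(ncol(trial$insole$cop_x)), function(j) {
    col <- trial$insole$cop_x[, j]
    ok <- !is.na(col)
    if (sum(ok) < 2L) return(rep(NA_real_, length(grid)))
    stats::approx(it[ok], col[ok], xout = grid, rule = 1)$y
  })
  cop[force < cop_mask_n] <- NA_real_

  knee <- list(time = grid,
               angle = resample_series(trial$knee$time, trial$knee$angle, grid))

  out <- trial
  out$kin <- out_kin
  out$insole <- list(time = grid, force = force, cop_x = cop)
  out$knee <- knee
  out$sync_offset <- 0
  attr(out, "fs") <- target_fs
  out
}

#' Smooth the synchronized streams
#'
#' Applies the zero-phase low-pass Butterworth to the kinematic channels,
#' the CoP and the knee angle. The raw force is left untouched: gait events
#' are detected from its sharp loading edges.
#'
#' @param trial synchronized [trial_recording()].
#' @param cutoff_hz cutoff (default 7 Hz).
#' @param order per-pass filter order (default 2).
#' @return the trial with smoothed channels.
#' @export
smooth_trial <- function(trial, cutoff_hz = 7, order = 2L) {
  fs <- attr(trial, "fs")
  if (is.null(fs)) stop("smooth_trial expects a synchronized trial", call. = FALSE)
  for (nm in c("pos_x", "pos_z", "vel_x", "vel_z", "orient", "angvel", "foot_y"))
    trial$kin[[nm]] <- butterworth_lowpass(trial$kin[[nm]], cutoff_hz, fs, order)
  trial$knee$angle <- butterworth_lowpass(trial$knee$angle, cutoff_hz, fs, order)
  # CoP: filter within loaded stretches only (NA elsewhere)
  cop <- trial$insole$cop_x
  for (j in seq_len(ncol(cop))) {
    ok <- !is.na(cop[, j])
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      if (length(idx) > 40L)
        cop[idx, j] <- butterworth_lowpass(cop[idx, j], cutoff_hz, fs, order)
    }
  }
  trial$insole$cop_x <- cop
  trial
}

#' Whole-body centre of mass from segment kinematics
#'
#' Mass-weighted mean of the 14 segment CoM positions and velocities. If the
#' kinematic stream carries no velocity channels the velocity falls back to
#' central differences of the CoM position.
#'
#' @param kin the `kin` element of a synchronized trial.
#' @param model a [build_body_model()] model (segment order must match).
#' @return list with `x`, `z`, `vx`, `vz` (numeric vectors on `kin$time`).
#' @export
whole_body_com <- function(kin, model) {
  if (!identical(nrow(model), length(segment_names())) ||
      !identical(model$segment, segment_names()))
    stop("model segments do not match the canonical 14-segment set", call. = FALSE)
  w <- model$mass / sum(model$mass)
  out <- list(x = drop(kin$pos_x %*% w), z = drop(kin$pos_z %*% w))
  if (!is.null(kin$vel_x)) {
    out$vx <- drop(kin$vel_x %*% w)
    out$vz <- drop(kin$vel_z %*% w)
  } else {
    dt <- stats::median(diff(kin$time))
    out$vx <- differentiate(out$x, dt)
    out$vz <- differentiate(out$z, dt)
  }
  out
}
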