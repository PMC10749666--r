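#' Zero-phase low-pass Butterworth filtering
#'
#' Second-order (by default) Butterworth smoothing applied forward and
#' backward, so the pass is zero-phase and event timing is not lagged. The
#' two passes double the attenuation: the nominal cutoff is the -6 dB point
#' (amplitude 0.5) of the combined filter. Ends are handled by odd
#' (point-reflected) padding.
#'
#' @param x numeric vector, or a matrix filtered column-wise.
#' @param cutoff_hz cutoff frequency in Hz (must be below Nyquist).
#' @param fs sampling rate in Hz.
#' @param order filter order of each pass (default 2).
#' @return filtered object of the same shape.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' y <- sin(2 * pi * 2 * t) + rnorm(length(t), sd = 0.2)
#' ys <- butterworth_lowpass(y, 7, 100)
#' @export
butterworth_lowpass <- function(x, cutoff_hz, fs, order = 2L) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie in (0, fs/2)", call. = FALSE)
  ba <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  npad <- 3L * (max(length(ba$b), length(ba$a)) - 1L) * 3L
  if (nrow(xm) <= npad)
    stop("signal too short for zero-phase filtering (need > ", npad,
         " samples)", call. = FALSE)
  out <- filtfilt_matrix(ba$b, ba$a, xm, npad)
  if (vec) drop(out) else out
}

# forward-backward IIR with odd-reflection padding, vectorised across
# columns. Columns are demeaned first: the zero-state transient scales with
# the signal's absolute level, and removing the mean makes the pass exactly
# invariant to constant offsets (the DC gain is 1).
filtfilt_matrix <- function(b, a, x, npad) {
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu)
  n <- nrow(x)
  pre <- 2 * x[rep(1L, npad), , drop = FALSE] - x[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * x[rep(n, npad), , drop = FALSE] - x[(n - 1L):(n - npad), , drop = FALSE]
  y <- rbind(pre, x, post)
  y <- iir_columns(b, a, y)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- iir_columns(b, a, y)
  y <- y[nrow(y):1L, , drop = FALSE]
  sweep(y[(npad + 1L):(npad + n), , drop = FALSE], 2L, mu, `+`)
}

# direct-form transposed II applied to every column; time loop, columns vectorised
iir_columns <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  nb <- length(b); na <- length(a)
  n <- nrow(x); p <- ncol(x)
  y <- matrix(0, n, p)
  z <- matrix(0, max(nb, na) - 1L, p)  # state
  nz <- nrow(z)
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (nz > 1L) {
      for (k in seq_len(nz - 1L)) {
        bk <- if (k + 1L <= nb) b[k + 1L] else 0
        ak <- if (k + 1L <= na) a[k + 1L] else 0
        z[k, ] <- bk * xt + z[k + 1L, ] - ak * yt
      }
    }
    bk <- if (nz + 1L <= nb) b[nz + 1L] else 0
    ak <- if (nz + 1L <= na) a[nz + 1L] else 0
    z[nz, ] <- bk * xt - ak * yt
    y[t, ] <- yt
  }
  y
}

#' Numerical differentiation on a uniform grid
#'
#' Central differences on the interior, one-sided at the two ends. Exact for
#' signals affine in time (interior and ends).
#'
#' @param x numeric vector or matrix (column-wise).
#' @param dt sample interval in seconds.
#' @return derivative of the same shape.
#' @export
differentiate <- function(x, dt) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  n <- nrow(xm)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- xm
  d[2:(n - 1L), ] <- (xm[3:n, , drop = FALSE] - xm[1:(n - 2L), , drop = FALSE]) / (2 * dt)
  d[1L, ] <- (xm[2L, ] - xm[1L, ]) / dt
  d[n, ] <- (xm[n, ] - xm[n - 1L, ]) / dt
  if (vec) drop(d) else d
}

#' Resample a uniformly sampled series onto a new time grid
#'
#' Cubic-spline interpolation (exact on affine signals, ~h^4 error on smooth
#' band-limited ones). Refuses to extrapolate.
#'
#' @param time sample times of `x` (strictly increasing).
#' @param x values, vector or matrix (rows are samples).
#' @param new_time target times, all within `range(time)`.
#' @return interpolated values at `new_time` (vector or matrix).
#' @export
resample_series <- function(time, x, new_time) {
  if (is.unsorted(time, strictly = TRUE))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (min(new_time) < time[1L] - 1e-9 || max(new_time) > time[length(time)] + 1e-9)
    stop("resample_series: target grid extends beyond the recorded span",
         call. = FALSE)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  out <- apply(xm, 2L, function(col)
    stats::spline(time, col, xout = new_time, method = "fmm")$y)
  out <- matrix(out, nrow = length(new_time))
  if (vec) drop(out) else out
}
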