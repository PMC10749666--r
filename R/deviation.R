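#' Build the normal-stride template for one metric
#'
#' Pointwise mean and sample SD over the normal (non-disturbed,
#' non-excluded) strides on the percent grid, plus the excursion
#' (max - min) of the mean trajectory. Grid points where fewer than half
#' the strides have data (stance-window metrics end at varying percents)
#' are dropped from the template.
#'
#' @param mat strides-by-percent matrix of normal-stride trajectories.
#' @param metric metric name carried in the result.
#' @param min_strides refuse to build a template from fewer strides.
#' @return object of class `normal_template`: list with `metric`, `mean`,
#'   `sd` (length-`ncol(mat)` vectors, NA off the valid support),
#'   `excursion`, `n_strides`.
#' @export
build_template <- function(mat, metric = "metric", min_strides = 20L) {
  mat <- mat[rowSums(is.finite(mat)) > 0L, , drop = FALSE]
  n <- nrow(mat)
  if (n < min_strides)
    stop(sprintf("build_template(%s): only %d normal strides, need >= %d",
                 metric, n, min_strides), call. = FALSE)
  cnt <- colSums(is.finite(mat))
  valid <- cnt >= n / 2
  mu <- sdv <- rep(NA_real_, ncol(mat))
  mu[valid] <- colMeans(mat[, valid, drop = FALSE], na.rm = TRUE)
  sdv[valid] <- apply(mat[, valid, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  exc <- max(mu, na.rm = TRUE) - min(mu, na.rm = TRUE)
  structure(list(metric = metric, mean = mu, sd = sdv,
                 excursion = exc, n_strides = n),
            class = "normal_template")
}

#' @export
print.normal_template <- function(x, ...) {
  cat(sprintf("<normal_template> %s: %d strides, excursion %.4g, support %d/%d points\n",
              x$metric, x$n_strides, x$excursion,
              sum(is.finite(x$mean)), length(x$mean)))
  invisible(x)
}

#' Deviation window of a disturbed stride
#'
#' The N-RMSE is evaluated from the disturbance onset to the end of the
#' prosthetic stance phase, both in percent of the disturbed stride.
#'
#' @param onset_pct disturbance onset (percent of gait cycle).
#' @param stance_end_pct stance end (percent of gait cycle).
#' @return numeric `c(start, end)` in percent.
#' @export
deviation_window <- function(onset_pct, stance_end_pct) {
  if (!is.finite(onset_pct) || !is.finite(stance_end_pct))
    stop("deviation_window: onset and stance end must be known", call. = FALSE)
  if (onset_pct >= stance_end_pct)
    stop("deviation_window: disturbance onset after stance end (swing-phase disturbance is out of protocol)",
         call. = FALSE)
  c(start = onset_pct, end = stance_end_pct)
}

#' Excursion-normalized RMSE of a stride against the normal template
#'
#' The template mean is resampled (linearly in percent) onto the stride's
#' grid points inside the window; the RMSE over those points is divided by
#' the template's excursion. Masked (NA) samples are excluded; an
#' all-masked window yields NA.
#'
#' @param values stride trajectory on the percent grid.
#' @param template [build_template()] result.
#' @param window `c(start, end)` percent window (default: full template
#'   support).
#' @param percent_grid the percent grid (default `seq(0, 100, length.out =
#'   length(values))`).
#' @return single non-negative N-RMSE value (NA if nothing to compare).
#' @export
nrmse <- function(values, template, window = NULL,
                  percent_grid = seq(0, 100, length.out = length(values))) {
  if (template$excursion <= 0)
    stop("nrmse: template excursion must be positive", call. = FALSE)
  sup <- is.finite(template$mean)
  if (is.null(window))
    window <- range(percent_grid[sup])
  idx <- percent_grid >= window[1] - 1e-9 & percent_grid <= window[2] + 1e-9
  if (!any(idx)) stop("nrmse: empty window", call. = FALSE)
  tm <- stats::approx(percent_grid[sup], template$mean[sup],
                      xout = percent_grid[idx], rule = 1)$y
  d <- values[idx] - tm
  ok <- is.finite(d)
  if (!any(ok)) return(NA_real_)
  sqrt(mean(d[ok]^2)) / template$excursion
}

#' Per-stride N-RMSE of the normal strides themselves
#'
#' The variation of normal gait about its own template: one N-RMSE per
#' normal stride over the metric's full valid window. By default the
#' template built from all strides is used; `leave_one_out = TRUE` rebuilds
#' the mean without the evaluated stride.
#'
#' @param mat strides-by-percent matrix of normal-stride trajectories.
#' @param template [build_template()] of those strides (built internally if
#'   `NULL`).
#' @param metric name for messages.
#' @param min_strides floor passed to [build_template()].
#' @param leave_one_out use a leave-one-out mean (default FALSE, mirroring
#'   the all-strides baseline).
#' @return numeric vector of per-stride N-RMSE values.
#' @export
normal_variability <- function(mat, template = NULL, metric = "metric",
                               min_strides = 20L, leave_one_out = FALSE) {
  if (is.null(template))
    template <- build_template(mat, metric, min_strides)
  n <- nrow(mat)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tpl <- template
    if (leave_one_out) {
      tpl <- build_template(mat[-i, , drop = FALSE], metric,
                            min_strides = min(min_strides, n - 1L))
      tpl$excursion <- template$excursion  # keep a common scale
    }
    out[i] <- nrmse(mat[i, ], tpl)
  }
  out
}
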