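#' Detect heel strikes and toe-offs from insole vertical force
#'
#' Heel strike (HS) at upward crossings of the force threshold, toe-off (TO)
#' at downward crossings, debounced by a minimum interval so brief unloading
#' spikes do not split a stance. The per-foot event train must alternate
#' HS, TO, HS, TO and every stance must last a physiological time.
#'
#' @param time uniform time grid (s).
#' @param force n-by-2 matrix of vertical force (N), columns left/right.
#' @param threshold_n crossing threshold in newtons (default 30).
#' @param debounce_s minimum spacing between a TO and the next HS and
#'   minimum stance/swing duration (default 0.05 s).
#' @return object of class `gait_events`: list with per-foot `hs` and `to`
#'   time vectors, elements `L` and `R`.
#' @export
detect_events <- function(time, force, threshold_n = 30, debounce_s = 0.05) {
  stopifnot(is.matrix(force), ncol(force) == 2L, nrow(force) == length(time))
  out <- list(hs = list(), to = list())
  for (j in 1:2) {
    side <- c("L", "R")[j]
    loaded <- force[, j] >= threshold_n
    if (!any(loaded))
      stop("detect_events: no force crossings on foot ", side, call. = FALSE)
    d <- diff(loaded)
    # sub-sample crossing times by linear interpolation across the
    # threshold (stride boundaries are generally not grid-aligned)
    cross_at <- function(i) {
      f0 <- force[i, j]; f1 <- force[i + 1L, j]
      if (f1 == f0) return(time[i + 1L])
      time[i] + (threshold_n - f0) / (f1 - f0) * (time[i + 1L] - time[i])
    }
    hs <- vapply(which(d == 1L), cross_at, numeric(1))
    to <- vapply(which(d == -1L), cross_at, numeric(1))
    # debounce: drop unload/reload pairs shorter than debounce_s
    ev <- rbind(data.frame(t = hs, e = "HS"), data.frame(t = to, e = "TO"))
    ev <- ev[order(ev$t), ]
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      if (keep[i] && ev$e[i] == "TO" && i + 1L <= nrow(ev) &&
          ev$e[i + 1L] == "HS" && ev$t[i + 1L] - ev$t[i] < debounce_s) {
        keep[i] <- keep[i + 1L] <- FALSE
        i <- i + 2L
      } else i <- i + 1L
    }
    ev <- ev[keep, ]
    # after debouncing the pattern must alternate
    if (nrow(ev) >= 2L && any(ev$e[-1L] == ev$e[-nrow(ev)]))
      stop("detect_events: non-alternating HS/TO pattern on foot ", side,
           call. = FALSE)
    hs <- ev$t[ev$e == "HS"]; to <- ev$t[ev$e == "TO"]
    # stance-duration sanity on complete HS->TO pairs
    for (h in hs) {
      nxt <- to[to > h]
      if (length(nxt)) {
        dur <- nxt[1L] - h
        if (dur <= 0.1 || dur >= 2.5)
          stop(sprintf("detect_events: stance of %.2f s on foot %s outside (0.1, 2.5) s",
                       dur, side), call. = FALSE)
      }
    }
    out$hs[[side]] <- hs
    out$to[[side]] <- to
  }
  structure(out, class = "gait_events")
}

#' Segment a trial into prosthetic strides with stance sub-phases
#'
#' One stride per consecutive pair of prosthetic heel strikes, half-open
#' `[HS, next HS)`. Stance ends at the prosthetic toe-off inside the stride;
#' stance is partitioned into initial double support (IDS: prosthetic HS to
#' contralateral TO), single support (SS: contralateral TO to contralateral
#' HS) and terminal double support (TDS: contralateral HS to prosthetic TO).
#' Strides missing the needed contralateral events are flagged unusable.
#'
#' @param events a [detect_events()] result.
#' @param side prosthetic side, `"L"` or `"R"`.
#' @return data.frame with one row per stride: `start`, `end`, `stance_end`,
#'   `ids_end`, `ss_end` (s; `ss_end == `contralateral HS, TDS runs to
#'   `stance_end`), `usable` flag.
#' @export
segment_strides <- function(events, side = c("L", "R")) {
  side <- match.arg(side)
  other <- setdiff(c("L", "R"), side)
  hs <- events$hs[[side]]
  if (length(hs) < 2L)
    stop("segment_strides: need at least 2 prosthetic heel strikes", call. = FALSE)
  n <- length(hs) - 1L
  res <- data.frame(stride = seq_len(n), start = hs[-length(hs)], end = hs[-1L],
                    stance_end = NA_real_, ids_end = NA_real_,
                    ss_end = NA_real_, usable = FALSE)
  for (i in seq_len(n)) {
    s <- res$start[i]; e <- res$end[i]
    pto <- events$to[[side]]
    pto <- pto[pto > s & pto < e]
    cto <- events$to[[other]]; cto <- cto[cto > s & cto < e]
    chs <- events$hs[[other]]; chs <- chs[chs > s & chs < e]
    if (length(pto) == 1L && length(cto) >= 1L && length(chs) >= 1L &&
        cto[1L] < chs[1L] && chs[1L] < pto[1L]) {
      res$stance_end[i] <- pto[1L]
      res$ids_end[i] <- cto[1L]
      res$ss_end[i] <- chs[1L]
      res$usable[i] <- TRUE
    }
  }
  res
}

#' Flag disturbed and template-excluded strides
#'
#' The stride whose half-open interval contains the disturbance onset is
#' flagged `disturbed`; the immediately following stride is flagged
#' `excluded` so neither enters the normal-gait template. An onset at a
#' stride boundary belongs to the later stride.
#'
#' @param strides a [segment_strides()] table.
#' @param disturbance disturbance log of the trial (or `NULL`).
#' @return the table with logical columns `disturbed` and `excluded` added.
#' @export
mark_disturbed <- function(strides, disturbance = NULL) {
  strides$disturbed <- FALSE
  strides$excluded <- FALSE
  if (is.null(disturbance)) return(strides)
  k <- which(disturbance$onset >= strides$start & disturbance$onset < strides$end)
  if (!length(k)) {
    warning("disturbance onset falls outside every stride; nothing flagged")
    return(strides)
  }
  strides$disturbed[k] <- TRUE
  if (k + 1L <= nrow(strides)) strides$excluded[k + 1L] <- TRUE
  strides
}

#' Time-normalize a trajectory onto the percent-gait-cycle grid
#'
#' Linear interpolation of a stride's native-time trajectory onto `n_points`
#' evenly spaced percents of the stride span (endpoints preserved).
#'
#' @param time native sample times (s), covering `[start, end]`.
#' @param values trajectory values at `time` (NA allowed; NA spans remain NA).
#' @param start,end stride boundaries (s).
#' @param n_points grid size (default 101: 0, 1, ..., 100 percent).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(time, values, start, end, n_points = 101L) {
  if (time[1L] > start + 1e-9 || time[length(time)] < end - 1e-9)
    stop("time_normalize: trajectory does not cover the stride span", call. = FALSE)
  tt <- seq(start, end, length.out = n_points)
  ok <- !is.na(values)
  if (sum(ok) < 2L) return(rep(NA_real_, n_points))
  out <- stats::approx(time[ok], values[ok], xout = tt, rule = 1)$y
  # keep NA where the source was locally NA (no bridging across masked gaps)
  if (any(!ok)) {
    na_at <- stats::approx(time, as.numeric(!ok), xout = tt, rule = 2)$y
    out[na_at > 0] <- NA_real_
  }
  out
}
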