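#' Write a trial to disk
#'
#' One long-format CSV (`time_s, channel, value`) holding every sample of
#' the three streams, plus a YAML sidecar with the anthropometrics, sync
#' offset, disturbance log and perception report. Channel names are
#' `<stream>.<field>.<segment-or-foot>`, e.g. `kin.pos_x.thigh_L`,
#' `insole.force.L`, `knee.angle`.
#'
#' @param x a [trial_recording()].
#' @param path_prefix files are written as `<path_prefix>.csv` and
#'   `<path_prefix>.yaml`.
#' @return `path_prefix`, invisibly.
#' @export
write_trial <- function(x, path_prefix) {
  stopifnot(inherits(x, "trial_recording"))
  rows <- list()
  add <- function(time, mat, prefix, cols) {
    for (j in seq_along(cols))
      rows[[length(rows) + 1L]] <<- data.frame(
        time_s = time, channel = paste(prefix, cols[j], sep = "."),
        value = mat[, j])
  }
  segs <- segment_names()
  for (f in c("pos_x", "pos_z", "vel_x", "vel_z", "orient", "angvel"))
    add(x$kin$time, x$kin[[f]], paste0("kin.", f), segs)
  add(x$kin$time, x$kin$foot_y, "kin.foot_y", c("L", "R"))
  add(x$insole$time, x$insole$force, "insole.force", c("L", "R"))
  add(x$insole$time, x$insole$cop_x, "insole.cop_x", c("L", "R"))
  rows[[length(rows) + 1L]] <- data.frame(
    time_s = x$knee$time, channel = "knee.angle", value = x$knee$angle)
  long <- do.call(rbind, rows)
  utils::write.csv(format(long, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   paste0(path_prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  side <- list(
    subject = x$subject, trial = x$trial,
    sync_offset = x$sync_offset,
    anthropometrics = list(
      height_m = x$anthro$height, mass_kg = x$anthro$mass,
      leg_length_m = x$anthro$leg_length,
      foot_length_m = x$anthro$foot_length,
      affected_side = x$anthro$affected_side),
    disturbance = x$disturbance,
    perception = x$perception)
  yaml::write_yaml(side, paste0(path_prefix, ".yaml"), precision = 15)
  invisible(path_prefix)
}

#' Read a trial written by [write_trial()]
#'
#' Validates the schema (required channels, shared monotone time grid per
#' stream) and reconstructs the [trial_recording()]. A missing perception
#' field is accepted (label-absent trial).
#'
#' @param path_prefix prefix used at write time.
#' @return a [trial_recording()].
#' @export
read_trial <- function(path_prefix) {
  long <- utils::read.csv(paste0(path_prefix, ".csv"),
                          stringsAsFactors = FALSE)
  if (!all(c("time_s", "channel", "value") %in% names(long)))
    stop("trial CSV must have columns time_s, channel, value", call. = FALSE)
  side <- yaml::read_yaml(paste0(path_prefix, ".yaml"))
  an <- anthropometrics(side$anthropometrics$height_m,
                        side$anthropometrics$mass_kg,
                        side$anthropometrics$leg_length_m,
                        side$anthropometrics$foot_length_m,
                        side$anthropometrics$affected_side)
  get_stream <- function(prefix, cols) {
    out <- NULL; time <- NULL
    for (j in seq_along(cols)) {
      ch <- paste(prefix, cols[j], sep = ".")
      d <- long[long$channel == ch, ]
      if (!nrow(d)) stop("missing channel ", ch, call. = FALSE)
      if (is.unsorted(d$time_s, strictly = TRUE))
        stop("non-monotone time grid in channel ", ch, call. = FALSE)
      if (is.null(time)) time <- d$time_s
      else if (length(d$time_s) != length(time) ||
               max(abs(d$time_s - time)) > 1e-9)
        stop("channel ", ch, " is not on its stream's shared grid",
             call. = FALSE)
      out <- cbind(out, d$value)
    }
    list(time = time, mat = out)
  }
  segs <- segment_names()
  kin <- list()
  for (f in c("pos_x", "pos_z", "vel_x", "vel_z", "orient", "angvel")) {
    st <- get_stream(paste0("kin.", f), segs)
    kin$time <- st$time; kin[[f]] <- st$mat
  }
  kin$foot_y <- get_stream("kin.foot_y", c("L", "R"))$mat
  fo <- get_stream("insole.force", c("L", "R"))
  cp <- get_stream("insole.cop_x", c("L", "R"))
  kn <- get_stream("knee", "angle")
  trial_recording(
    kin = kin,
    insole = list(time = fo$time, force = fo$mat, cop_x = cp$mat),
    knee = list(time = kn$time, angle = drop(kn$mat)),
    anthro = an, disturbance = side$disturbance,
    perception = side$perception,
    sync_offset = side$sync_offset %||% 0,
    subject = side$subject %||% "S01", trial = side$trial %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys raise an
#' error, and every value is validated by the constructor.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Write a result bundle to a directory
#'
#' Tidy CSVs for the deviation, association and selection tables and the
#' per-subject normal templates, plus JSON for the SPM partitions and the
#' manifest.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "gaitstab_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  if (nrow(result$deviation)) wcsv(result$deviation, "deviation.csv")
  if (!is.null(result$association)) wcsv(result$association, "association.csv")
  if (!is.null(result$selection)) wcsv(result$selection, "selection.csv")
  tpl_rows <- list()
  for (sub in names(result$templates))
    for (m in metric_names_trajectory()) {
      tpl <- result$templates[[sub]][[m]]
      tpl_rows[[length(tpl_rows) + 1L]] <- data.frame(
        subject = sub, metric = m,
        percent = seq(0, 100, length.out = length(tpl$mean)),
        mean = tpl$mean, sd = tpl$sd)
    }
  if (length(tpl_rows)) wcsv(do.call(rbind, tpl_rows), "templates.csv")
  spm_json <- lapply(result$spm, function(s)
    list(partition = s$partition_string,
         comparisons = s$comparisons))
  jsonlite::write_json(spm_json, file.path(dir, "spm.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(majority_partition = lapply(result$majority_partition, identity),
         discarded = result$discarded, manifest = result$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  invisible(dir)
}
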