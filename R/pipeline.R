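#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the protocol
#' defaults: 7 Hz second-order zero-phase Butterworth smoothing, a 100 Hz
#' analysis grid, 30 N event threshold with 50 ms debounce, the 101-point
#' percent-cycle grid, a 20-stride template floor, permutation SPM at
#' alpha = 0.05 on the A-P CoP, and the tau-significance / pseudo-R2 > 0.2
#' selection rule.
#'
#' @param filter_order,filter_cutoff_hz smoothing filter settings.
#' @param fs analysis rate (Hz).
#' @param event_threshold_n,event_debounce_s insole event detection.
#' @param n_points percent-grid size.
#' @param template_min_strides normal-template floor.
#' @param spm_alpha,spm_nperm,spm_metric SPM settings; `spm_metric` names
#'   the metric whose trajectories drive condition merging.
#' @param tau_alpha,r2_min metric-selection rule.
#' @param g gravitational acceleration (m/s^2).
#' @param seed RNG seed for the permutation SPM.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_order = 2L, filter_cutoff_hz = 7,
                            fs = 100, event_threshold_n = 30,
                            event_debounce_s = 0.05, n_points = 101L,
                            template_min_strides = 20L,
                            spm_alpha = 0.05, spm_nperm = 2000L,
                            spm_metric = "ap_cop",
                            tau_alpha = 0.05, r2_min = 0.2,
                            g = 9.81, seed = 1L) {
  stopifnot(filter_cutoff_hz > 0, filter_cutoff_hz < fs / 2,
            n_points >= 11L, spm_alpha > 0, spm_alpha < 1,
            spm_metric %in% metric_names())
  structure(as.list(environment()), class = "pipeline_config")
}

process_trial <- function(trial, model, cfg) {
  tr <- synchronize(trial, cfg$fs, cfg$event_threshold_n)
  tr <- smooth_trial(tr, cfg$filter_cutoff_hz, cfg$filter_order)
  compute_stride_metrics(tr, model, cfg$n_points,
                         cfg$event_threshold_n, cfg$event_debounce_s, cfg$g)
}

#' Run the full analysis pipeline
#'
#' Per subject: processes every trial (synchronize, smooth, detect events,
#' segment strides, compute metrics), builds normal-stride templates,
#' excursion-normalizes MoS and inclination angle, computes the N-RMSE of
#' every disturbed stride over its onset-to-stance-end window, merges
#' disturbance conditions via intensity-matched permutation SPM on
#' `spm_metric`, and relates N-RMSE to perception (Kendall tau, quadratic
#' binomial GLM, McFadden pseudo-R2) within the merged groups. The merged
#' partition applied to the association stage is the one the majority of
#' subjects reach.
#'
#' @param dataset a [generate_cohort()] object, or a list of
#'   [trial_recording()]s (they are grouped by their `subject` field).
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return object of class `gaitstab_result`: list with `templates` (per
#'   subject, per metric), `normal_variability`, `deviation` (data.frame),
#'   `spm` (per subject: comparisons + partition), `majority_partition`,
#'   `association` (data.frame), `selection` (data.frame), `discarded`
#'   (per-subject unusable-stride counts), `manifest`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  subjects <- dataset_subjects(dataset)
  traj_metrics <- metric_names_trajectory()
  exc_metrics <- c("mos", "inclination")
  pct <- seq(0, 100, length.out = config$n_points)

  templates <- list(); devrows <- list(); spm_out <- list()
  normvar <- list(); discarded <- list()

  for (su in subjects) {
    say("subject %s: processing %d trials", su$subject, su$n_trials)
    metas <- vector("list", su$n_trials)
    trajs <- lapply(traj_metrics, function(m) vector("list", su$n_trials))
    names(trajs) <- traj_metrics
    model <- build_body_model(su$anthro)
    for (k in seq_len(su$n_trials)) {
      res <- process_trial(su$get_trial(k), model, config)
      metas[[k]] <- res$meta
      for (m in traj_metrics) trajs[[m]][[k]] <- res$traj[[m]]
    }
    meta <- do.call(rbind, metas)
    traj <- lapply(trajs, function(l) do.call(rbind, l))
    discarded[[su$subject]] <- sum(!meta$usable)

    normal <- meta$usable & !meta$disturbed & !meta$excluded
    disturbed <- meta$usable & meta$disturbed & is.finite(meta$onset_pct)

    tpls <- list()
    for (m in traj_metrics) {
      tpl <- build_template(traj[[m]][normal, , drop = FALSE], m,
                            config$template_min_strides)
      if (m %in% exc_metrics) {
        e <- tpl$excursion
        traj[[m]] <- traj[[m]] / e
        tpl$mean <- tpl$mean / e; tpl$sd <- tpl$sd / e
        tpl$excursion <- 1
      }
      tpls[[m]] <- tpl
    }
    # scalar "templates": normal-stride distribution summaries
    for (m in metric_names_scalar()) {
      v <- meta[[m]][normal]
      tpls[[m]] <- list(metric = m, mean = mean(v, na.rm = TRUE),
                        range = diff(range(v, na.rm = TRUE)),
                        n_strides = sum(is.finite(v)))
    }
    templates[[su$subject]] <- tpls
    normvar[[su$subject]] <- lapply(traj_metrics, function(m)
      normal_variability(traj[[m]][normal, , drop = FALSE], tpls[[m]], m,
                         config$template_min_strides))
    names(normvar[[su$subject]]) <- traj_metrics

    say("subject %s: %d normal / %d disturbed strides",
        su$subject, sum(normal), sum(disturbed))

    # --- deviation table
    didx <- which(disturbed)
    for (i in didx) {
      win <- deviation_window(meta$onset_pct[i], meta$stance_end_pct[i])
      for (m in traj_metrics) {
        devrows[[length(devrows) + 1L]] <- data.frame(
          subject = su$subject, trial = meta$trial[i], stride = meta$stride[i],
          metric = m, type = meta$type[i], timing = meta$timing[i],
          intensity = meta$intensity[i], perception = meta$perception[i],
          window_start = win[1], window_end = win[2],
          nrmse = nrmse(traj[[m]][i, ], tpls[[m]], win, pct))
      }
      for (m in metric_names_scalar()) {
        devrows[[length(devrows) + 1L]] <- data.frame(
          subject = su$subject, trial = meta$trial[i], stride = meta$stride[i],
          metric = m, type = meta$type[i], timing = meta$timing[i],
          intensity = meta$intensity[i], perception = meta$perception[i],
          window_start = win[1], window_end = win[2],
          nrmse = if (tpls[[m]]$range > 0)
            abs(meta[[m]][i] - tpls[[m]]$mean) / tpls[[m]]$range
          else NA_real_)
      }
    }

    # --- SPM condition merging on the configured metric
    spm_out[[su$subject]] <- spm_merge_subject(
      meta, traj[[config$spm_metric]], disturbed, config, pct)
  }

  deviation <- if (length(devrows)) do.call(rbind, devrows) else
    data.frame()

  # cohort-level partition: the one most subjects reach
  part_strings <- vapply(spm_out, function(s) s$partition_string, character(1))
  majority_string <- names(sort(table(part_strings), decreasing = TRUE))[1L]
  majority_groups <- spm_out[[which(part_strings == majority_string)[1L]]]$merge$groups

  # --- association within merged groups
  association <- NULL
  if (nrow(deviation) > 0L && any(!is.na(deviation$perception))) {
    association <- associate_groups(deviation, majority_groups, config)
  } else {
    say("no disturbed strides with perception labels; association skipped")
  }
  selection <- if (!is.null(association)) {
    ok <- is.finite(association$tau_p) | is.finite(association$pseudo_r2)
    select_metrics(association[ok, ], config$tau_alpha, config$r2_min)
  } else NULL

  structure(list(
    templates = templates, normal_variability = normvar,
    deviation = deviation, spm = spm_out,
    majority_partition = majority_groups,
    association = association, selection = selection,
    discarded = discarded,
    manifest = list(config = unclass(config),
                    n_subjects = length(subjects),
                    seed = config$seed)),
    class = "gaitstab_result")
}

# intensity-matched SPM comparisons and merge for one subject
spm_merge_subject <- function(meta, traj_m, disturbed, config, pct) {
  cell <- function(type, timing) paste(type, timing, sep = ".")
  meta$cell <- cell(meta$type, meta$timing)
  comps <- list(); rows <- list()
  pairs <- rbind(
    # same type, different timing
    expand.grid(a_type = c("flexion", "extension"), a_tim = "IDS",
                b_tim = "SS", stringsAsFactors = FALSE) |>
      transform(b_type = a_type),
    # same timing, different type
    expand.grid(a_tim = c("IDS", "SS"), a_type = "flexion",
                b_type = "extension", stringsAsFactors = FALSE) |>
      transform(b_tim = a_tim))
  with_seed(config$seed, {
    for (k in seq_len(nrow(pairs))) {
      for (lev in 1:3) {
        ia <- disturbed & meta$type == pairs$a_type[k] &
          meta$timing == pairs$a_tim[k] & meta$intensity == lev
        ib <- disturbed & meta$type == pairs$b_type[k] &
          meta$timing == pairs$b_tim[k] & meta$intensity == lev
        if (sum(ia) < 5L || sum(ib) < 5L) next
        both_ss <- pairs$a_tim[k] == "SS" && pairs$b_tim[k] == "SS"
        onset_ref <- if (both_ss) meta$onset_pct[ia | ib] else
          meta$onset_pct[(ia | ib) & meta$timing == "IDS"]
        win <- c(stats::median(onset_ref),
                 stats::median(meta$stance_end_pct[ia | ib]))
        sr <- spm_compare(traj_m[ia, , drop = FALSE],
                          traj_m[ib, , drop = FALSE],
                          window = win, alpha = config$spm_alpha,
                          nperm = config$spm_nperm, percent_grid = pct)
        comps[[length(comps) + 1L]] <- sr
        rows[[length(rows) + 1L]] <- data.frame(
          cell_a = cell(pairs$a_type[k], pairs$a_tim[k]),
          cell_b = cell(pairs$b_type[k], pairs$b_tim[k]),
          intensity = lev, significant = sr$significant)
      }
    }
  })
  if (!length(rows)) {
    # nothing comparable (too few strides per condition): leave the
    # observed cells unmerged
    cells_present <- sort(unique(meta$cell[disturbed]))
    groups <- as.list(cells_present)
    names(groups) <- cells_present
    return(list(comparisons = NULL, results = list(),
                merge = list(partition = seq_along(groups), groups = groups),
                partition_string = paste(cells_present, collapse = " | ")))
  }
  ctab <- do.call(rbind, rows)
  mg <- merge_conditions(ctab)
  gs <- vapply(mg$groups, function(g) paste(sort(g), collapse = "+"),
               character(1))
  list(comparisons = ctab, results = comps, merge = mg,
       partition_string = paste(sort(gs), collapse = " | "))
}

associate_groups <- function(deviation, groups, config) {
  deviation$cell <- paste(deviation$type, deviation$timing, sep = ".")
  rows <- list()
  for (gname in names(groups)) {
    cells <- groups[[gname]]
    for (sub in unique(deviation$subject)) {
      for (m in unique(deviation$metric)) {
        d <- deviation[deviation$subject == sub & deviation$metric == m &
                         deviation$cell %in% cells &
                         !is.na(deviation$perception) &
                         is.finite(deviation$nrmse), ]
        row <- data.frame(subject = sub, metric = m, group = gname,
                          n = nrow(d), tau = NA_real_, tau_p = NA_real_,
                          b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                          pseudo_r2 = NA_real_, converged = NA,
                          note = "")
        pl <- perception_levels(d$perception)
        kt <- tryCatch(kendall_tau(d$nrmse, pl$level), error = function(e) e)
        if (!inherits(kt, "error")) {
          row$tau <- kt$tau; row$tau_p <- kt$p_value
        } else row$note <- conditionMessage(kt)
        gf <- tryCatch(fit_glm(d$nrmse, pl$perceivable), error = function(e) e)
        if (!inherits(gf, "error")) {
          row$b0 <- gf$coefficients[1]; row$b1 <- gf$coefficients[2]
          row$b2 <- gf$coefficients[3]
          # a diverged/separated fit carries no usable goodness of fit
          row$pseudo_r2 <- if (gf$converged) gf$pseudo_r2 else NA_real_
          row$converged <- gf$converged
          if (!gf$converged) row$note <- "glm did not converge (separation?)"
        } else row$note <- paste(row$note, conditionMessage(gf))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# normalize the two accepted dataset forms into a per-subject accessor list
dataset_subjects <- function(dataset) {
  if (inherits(dataset, "gait_cohort")) {
    lapply(seq_along(dataset$subjects), function(i) {
      su <- dataset$subjects[[i]]
      list(subject = su$subject, anthro = su$anthro,
           n_trials = nrow(su$schedule),
           get_trial = function(k) realize_trial(dataset, i, k)$trial)
    })
  } else if (is.list(dataset) && all(vapply(dataset, inherits, logical(1),
                                            "trial_recording"))) {
    subs <- vapply(dataset, function(tr) tr$subject, character(1))
    lapply(unique(subs), function(s) {
      trials <- dataset[subs == s]
      list(subject = s, anthro = trials[[1L]]$anthro,
           n_trials = length(trials),
           get_trial = function(k) trials[[k]])
    })
  } else stop("dataset must be a gait_cohort or a list of trial_recordings",
              call. = FALSE)
}

#' @export
print.gaitstab_result <- function(x, ...) {
  cat(sprintf("<gaitstab_result> %d subjects, %d disturbed stride-metric rows\n",
              x$manifest$n_subjects, nrow(x$deviation)))
  cat("merged condition groups:",
      paste(names(x$majority_partition), collapse = ", "), "\n")
  if (!is.null(x$selection)) {
    sel <- x$selection[x$selection$selected, ]
    if (nrow(sel))
      cat("metrics associated with perception (majority rule):\n",
          paste(sprintf("  %s [%s]: %d/%d subjects", sel$metric, sel$group,
                        sel$n_pass, sel$n_subjects), collapse = "\n"), "\n")
    else cat("no metric passed the majority selection rule\n")
  }
  invisible(x)
}
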