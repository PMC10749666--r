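#' Ordinal perception labels
#'
#' Maps the four report categories to ordinal levels 0-3 and the
#' perceivability dichotomy: "medium" and "large" reports are perceivable,
#' "none" and "small" are not.
#'
#' @param labels character vector of reports.
#' @return data.frame with `label`, `level` (0-3 integer) and `perceivable`
#'   (logical).
#' @export
perception_levels <- function(labels) {
  lv <- c(none = 0L, small = 1L, medium = 2L, large = 3L)
  if (any(!labels %in% names(lv)))
    stop("unknown perception label(s): ",
         paste(setdiff(labels, names(lv)), collapse = ", "), call. = FALSE)
  level <- unname(lv[labels])
  data.frame(label = labels, level = level, perceivable = level >= 2L,
             stringsAsFactors = FALSE)
}

#' Kendall correlation between N-RMSE and ordinal perception
#'
#' Tie-corrected Kendall tau-b with a two-sided p-value from the
#' tie-corrected normal approximation (heavy ties are inherent to ordinal
#' levels), via [stats::cor.test()].
#'
#' @param x continuous values (N-RMSE of one metric).
#' @param levels ordinal perception levels (integers 0-3 or a factor).
#' @return list with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, levels) {
  levels <- as.numeric(levels)
  ok <- is.finite(x) & is.finite(levels)
  x <- x[ok]; levels <- levels[ok]
  if (length(x) < 10L)
    stop("kendall_tau: need at least 10 observations", call. = FALSE)
  if (length(unique(levels)) < 2L)
    stop("kendall_tau: perception labels are constant; correlation undefined",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("kendall_tau: metric values are constant; correlation undefined",
         call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, levels, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Quadratic binomial GLM for perceivable disturbances
#'
#' Maximum-likelihood logistic regression of the perceivable/imperceptible
#' dichotomy on the N-RMSE with intercept, linear and quadratic terms:
#' `P(perceivable) = logistic(b0 + b1 x + b2 x^2)`. The quadratic term lets
#' the probability rise and saturate. Complete or quasi-complete separation
#' is flagged rather than silently reported.
#'
#' @param x N-RMSE values.
#' @param perceivable logical (or 0/1) outcomes.
#' @return object of class `perception_glm`: list with `coefficients`
#'   (b0, b1, b2), `vcov`, `log_lik`, `null_log_lik`, `pseudo_r2`, `n`,
#'   `converged`, `separation`, and the underlying `fit`.
#' @export
fit_glm <- function(x, perceivable) {
  y <- as.integer(perceivable)
  ok <- is.finite(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L)
    stop("fit_glm: need at least 10 observations", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("fit_glm: both outcome classes must be present", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm(y ~ x + I(x^2), family = stats::binomial(), data = dat),
    warning = function(cond) {
      w <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    })
  separation <- !is.null(w) &&
    grepl("fitted probabilities numerically 0 or 1", w)
  separation <- separation || any(abs(stats::coef(fit)) > 1e3)
  null_fit <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  out <- list(coefficients = stats::setNames(stats::coef(fit),
                                             c("b0", "b1", "b2")),
              vcov = stats::vcov(fit),
              log_lik = ll, null_log_lik = ll0,
              n = length(y),
              converged = fit$converged && !separation,
              separation = separation,
              fit = fit)
  out$pseudo_r2 <- pseudo_r2(out)
  class(out) <- "perception_glm"
  out
}

#' @export
print.perception_glm <- function(x, ...) {
  cat(sprintf("<perception_glm> n=%d, b=(%.3f, %.3f, %.3f), McFadden R2=%.3f%s\n",
              x$n, x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$pseudo_r2,
              if (!x$converged) " [NOT CONVERGED / SEPARATION]" else ""))
  invisible(x)
}

#' Predicted perceivability probability of a fitted model
#'
#' @param object a [fit_glm()] result.
#' @param newdata numeric vector of N-RMSE values.
#' @param ... unused.
#' @return probabilities in (0, 1).
#' @export
predict.perception_glm <- function(object, newdata, ...) {
  b <- object$coefficients
  stats::plogis(b[1] + b[2] * newdata + b[3] * newdata^2)
}

#' McFadden pseudo-R-squared
#'
#' `1 - LL_model / LL_null`, the convention behind the 0.2
#' good-fit benchmark used for metric selection.
#'
#' @param fit a [fit_glm()] result (or any list with `log_lik` and
#'   `null_log_lik`).
#' @return value in \[0, 1).
#' @export
pseudo_r2 <- function(fit) {
  if (!is.finite(fit$null_log_lik) || fit$null_log_lik == 0)
    stop("pseudo_r2: degenerate null log-likelihood", call. = FALSE)
  max(0, 1 - fit$log_lik / fit$null_log_lik)
}

#' Metric selection across subjects
#'
#' Per metric and disturbance group, counts the subjects whose Kendall
#' correlation is significant (two-sided p < `alpha`) and whose McFadden
#' pseudo-R-squared exceeds `r2_min`; a metric is flagged associated when a
#' strict majority of subjects pass.
#'
#' @param results data.frame with columns `subject`, `metric`, `group`,
#'   `tau_p`, `pseudo_r2`.
#' @param alpha tau significance level (default 0.05).
#' @param r2_min pseudo-R2 benchmark (default 0.2).
#' @return data.frame per metric-by-group: `n_subjects`, `n_pass`,
#'   `selected`.
#' @export
select_metrics <- function(results, alpha = 0.05, r2_min = 0.2) {
  need <- c("subject", "metric", "group", "tau_p", "pseudo_r2")
  stopifnot(all(need %in% names(results)))
  if (nrow(results) == 0L)
    return(data.frame(metric = character(0), group = character(0),
                      n_subjects = integer(0), n_pass = integer(0),
                      selected = logical(0)))
  out <- do.call(rbind, lapply(
    split(results, list(results$metric, results$group), drop = TRUE),
    function(d) {
      ns <- length(unique(d$subject))
      pass <- is.finite(d$tau_p) & d$tau_p < alpha &
        is.finite(d$pseudo_r2) & d$pseudo_r2 > r2_min
      np <- length(unique(d$subject[pass]))
      data.frame(metric = d$metric[1], group = d$group[1],
                 n_subjects = ns, n_pass = np,
                 selected = np > ns / 2)
    }))
  rownames(out) <- NULL
  out[order(out$group, -out$n_pass, out$metric), ]
}

#' Across-subject summary of perception-report counts
#'
#' Mean and sample (n-1) standard deviation of the number of reports per
#' perception level, both rounded to the nearest integer — the descriptive
#' bottom-row statistics of a per-subject report-count table.
#'
#' @param counts data.frame with a `subject` column and one column per
#'   perception level (e.g. `none`, `small`, `medium`, `large`).
#' @return data.frame with `level`, `mean`, `sd` (integers).
#' @export
table2_summary <- function(counts) {
  stopifnot("subject" %in% names(counts))
  if (anyNA(counts)) stop("missing counts for some subject", call. = FALSE)
  lv <- setdiff(names(counts), "subject")
  if (nrow(counts) < 2L)
    stop("table2_summary: sample SD undefined for a single subject", call. = FALSE)
  data.frame(
    level = lv,
    mean = vapply(lv, function(l) round(mean(counts[[l]])), numeric(1)),
    sd = vapply(lv, function(l) round(stats::sd(counts[[l]])), numeric(1)),
    row.names = NULL)
}
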