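test_that("perception labels map to ordinal levels and perceivability", {
  p <- perception_levels(c("none", "small", "medium", "large"))
  expect_equal(p$level, 0:3)
  expect_equal(p$perceivable, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(perception_levels("huge"), "unknown")
})

test_that("Kendall tau matches hand-checkable orderings", {
  # untied, perfectly concordant / discordant
  x <- (1:12) + 0.1
  y <- 1:12
  expect_equal(kendall_tau(x, y)$tau, 1)
  expect_equal(kendall_tau(rev(x), y)$tau, -1)
  # fully concordant continuous values against tied ordinal levels: tau-b
  # equals the tie-corrected pair enumeration, (n0 - ty)/sqrt(n0 (n0 - ty))
  xi <- 1:10; yi <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 3)
  kt <- kendall_tau(xi, yi)
  expect_equal(kt$tau, brute_tau_b(xi, yi), tolerance = 1e-10)
  expect_gt(kt$tau, 0.85)
  expect_lt(kt$p_value, 0.01)
  lv <- rep(0:3, each = 3)
  expect_error(kendall_tau(x, rep(1, 12)), "constant")
  expect_error(kendall_tau(rep(2, 12), lv), "constant")
  expect_error(kendall_tau(1:5, c(0, 1, 0, 1, 0)), "at least 10")
})

test_that("tau-b equals brute-force pair enumeration under heavy ties", {
  set.seed(9)
  for (r in 1:20) {
    n <- sample(10:50, 1)
    x <- round(rnorm(n), 1)          # ties in x too
    y <- sample(0:3, n, replace = TRUE)
    if (length(unique(y)) < 2 || sd(x) == 0) next
    expect_equal(kendall_tau(x, y)$tau, brute_tau_b(x, y), tolerance = 1e-10)
  }
})

test_that("the quadratic binomial GLM fits and flags degeneracies", {
  set.seed(3)
  x <- runif(300, 0, 2)
  p <- plogis(-3 + 4 * x)
  y <- rbinom(300, 1, p)
  fit <- fit_glm(x, y)
  expect_true(fit$converged)
  expect_equal(unname(predict(fit, 0)), unname(plogis(fit$coefficients[1])))
  expect_true(all(predict(fit, seq(0, 2, 0.1)) > 0 &
                    predict(fit, seq(0, 2, 0.1)) < 1))
  expect_error(fit_glm(x, rep(0, 300)), "both outcome classes")
  # complete separation is flagged, not silently reported
  xs <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  ys <- rep(c(0, 1), each = 20)
  fs <- fit_glm(xs, ys)
  expect_true(fs$separation)
  expect_false(fs$converged)
})

test_that("McFadden pseudo-R2 follows its definition and nesting order", {
  expect_equal(pseudo_r2(list(log_lik = -50, null_log_lik = -100)), 0.5)
  expect_error(pseudo_r2(list(log_lik = -1, null_log_lik = 0)), "degenerate")
  set.seed(12)
  x <- runif(200, 0, 2)
  y <- rbinom(200, 1, plogis(-1 + 1.5 * x))
  full <- fit_glm(x, y)
  lin <- stats::glm(y ~ x, family = stats::binomial())
  r2_lin <- 1 - as.numeric(stats::logLik(lin)) / full$null_log_lik
  expect_gte(full$pseudo_r2 + 1e-12, r2_lin)  # quadratic never fits worse
  # labels independent of x: pseudo-R2 near zero
  y0 <- rbinom(200, 1, 0.4)
  expect_lt(fit_glm(x, y0)$pseudo_r2, 0.05)
})

test_that("GLM parameter recovery covers the truth at nominal rates", {
  set.seed(77)
  truth <- c(-3, 4, 0)
  inside <- matrix(FALSE, 30, 3)
  for (r in 1:30) {
    x <- runif(500, 0, 2)
    eta <- truth[1] + truth[2] * x + truth[3] * x^2
    y <- rbinom(500, 1, plogis(eta))
    f <- fit_glm(x, y)
    se <- sqrt(diag(f$vcov))
    inside[r, ] <- abs(f$coefficients - truth) <= 1.96 * se
  }
  expect_gte(min(colSums(inside)), 25L)  # ~95% nominal, allow MC slack
})

test_that("metric selection requires a strict majority of passing subjects", {
  res <- expand.grid(subject = sprintf("S%02d", 1:7),
                     metric = c("knee_momentum", "vcom"),
                     group = "flexion", stringsAsFactors = FALSE)
  res$tau_p <- 0.5; res$pseudo_r2 <- 0
  res$tau_p[res$metric == "knee_momentum"][1:4] <- 0.01
  res$pseudo_r2[res$metric == "knee_momentum"][1:4] <- 0.35
  sel <- select_metrics(res)
  expect_true(sel$selected[sel$metric == "knee_momentum"])
  expect_equal(sel$n_pass[sel$metric == "knee_momentum"], 4L)
  expect_false(sel$selected[sel$metric == "vcom"])
  # a tie at exactly n/2 (even n) is not a majority
  res6 <- res[res$subject != "S07" & res$metric == "knee_momentum", ]
  res6$tau_p <- 0.5; res6$pseudo_r2 <- 0
  res6$tau_p[1:3] <- 0.01; res6$pseudo_r2[1:3] <- 0.3
  expect_false(select_metrics(res6)$selected)
})

test_that("the report-count summary reproduces printed descriptive statistics", {
  counts <- utils::read.csv(system.file("extdata", "perception_counts.csv",
                                        package = "gaitstab"))
  s <- table2_summary(counts)
  expect_equal(s$mean[s$level == "none"], 29)
  expect_equal(s$sd[s$level == "none"], 17)
  expect_equal(s$mean[s$level == "small"], 52)
  expect_equal(s$sd[s$level == "small"], 12)
  expect_equal(s$mean[s$level == "large"], 29)
  expect_equal(s$sd[s$level == "large"], 14)
  expect_error(table2_summary(counts[1, ]), "single subject")
  counts$none[2] <- NA
  expect_error(table2_summary(counts), "missing")
})
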