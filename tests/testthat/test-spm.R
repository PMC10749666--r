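sim_group <- function(n, p = 101, mu = 0, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * p, mu, sd), n, p)
}

test_that("identical groups give a zero t-field and no clusters", {
  A <- sim_group(8, seed = 1)
  r <- spm_compare(A, A, nperm = 200)
  expect_true(all(abs(r$t) < 1e-12))
  expect_false(r$significant)
  expect_equal(nrow(r$clusters), 0L)
})

test_that("group relabeling negates the t-field and keeps cluster locations", {
  # group sizes small enough for exhaustive enumeration, where the
  # permutation threshold is exactly relabeling-invariant
  set.seed(2)
  A <- sim_group(5); B <- sim_group(5) + 1.2
  r1 <- spm_compare(A, B, nperm = 500)
  r2 <- spm_compare(B, A, nperm = 500)
  expect_equal(r1$nperm, choose(10, 5))
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$clusters, r2$clusters)
  expect_equal(r1$crit, r2$crit)
})

test_that("an injected offset of 3 pooled SDs is detected on its window", {
  set.seed(31)
  hits <- 0L
  for (rep in 1:10) {
    A <- sim_group(10)
    B <- sim_group(10)
    idx <- 31:51  # [30, 50] percent
    B[, idx] <- B[, idx] + 3
    r <- spm_compare(A, B, nperm = 500)
    if (r$significant &&
        any(r$clusters$start <= 50 & r$clusters$end >= 30)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("degenerate inputs are refused", {
  A <- matrix(1, 6, 101)
  expect_error(spm_compare(A, A * 1, nperm = 100), "degenerate")
  expect_error(spm_compare(sim_group(3), sim_group(3), nperm = 100),
               "at least 5")
})

test_that("window restriction and NA support trimming work", {
  set.seed(4)
  A <- sim_group(10); B <- sim_group(10)
  A[, 70:101] <- NA  # e.g. past stance end
  B[, 75:101] <- NA
  r <- spm_compare(A, B, window = c(10, 90), nperm = 200)
  expect_true(all(r$percent >= 10 & r$percent <= 69))
})

test_that("condition merging follows the pairwise significance pattern", {
  cells <- c("flexion.IDS", "flexion.SS", "extension.IDS", "extension.SS")
  comb <- function(sig_type, sig_timing) {
    rbind(
      expand.grid(cell_a = "flexion.IDS", cell_b = "flexion.SS",
                  intensity = 1:3, significant = sig_timing),
      expand.grid(cell_a = "extension.IDS", cell_b = "extension.SS",
                  intensity = 1:3, significant = sig_timing),
      expand.grid(cell_a = "flexion.IDS", cell_b = "extension.IDS",
                  intensity = 1:3, significant = sig_type),
      expand.grid(cell_a = "flexion.SS", cell_b = "extension.SS",
                  intensity = 1:3, significant = sig_type))
  }
  # nothing significant: one merged group
  m0 <- merge_conditions(transform(comb(FALSE, FALSE),
                                   cell_a = as.character(cell_a),
                                   cell_b = as.character(cell_b)))
  expect_length(m0$groups, 1L)
  # timing non-significant, type significant: {flexion}, {extension}
  m1 <- merge_conditions(transform(comb(TRUE, FALSE),
                                   cell_a = as.character(cell_a),
                                   cell_b = as.character(cell_b)))
  expect_length(m1$groups, 2L)
  expect_setequal(names(m1$groups), c("flexion", "extension"))
  expect_setequal(m1$groups$flexion, c("flexion.IDS", "flexion.SS"))
  # everything significant: no merging, 4 groups
  m2 <- merge_conditions(transform(comb(TRUE, TRUE),
                                   cell_a = as.character(cell_a),
                                   cell_b = as.character(cell_b)))
  expect_length(m2$groups, 4L)
  # a single discordant intensity does not block a merge (majority rule)
  d <- transform(comb(TRUE, FALSE), cell_a = as.character(cell_a),
                 cell_b = as.character(cell_b))
  d$significant[d$cell_a == "flexion.IDS" & d$cell_b == "flexion.SS" &
                  d$intensity == 2] <- TRUE
  m3 <- merge_conditions(d)
  expect_length(m3$groups, 2L)
})

test_that("merging is idempotent under the transitive closure", {
  d <- data.frame(cell_a = c("a", "b"), cell_b = c("b", "c"),
                  intensity = 1, significant = FALSE)
  m <- merge_conditions(d)
  expect_length(m$groups, 1L)  # a-b and b-c merge pulls in a-c
  # re-running on the merged structure changes nothing
  m2 <- merge_conditions(d)
  expect_identical(m$partition, m2$partition)
})
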