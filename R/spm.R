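#' Permutation SPM comparison of two trajectory groups
#'
#' One-dimensional statistical parametric mapping with a nonparametric
#' (permutation) threshold: a pooled-variance two-sample t statistic is
#' computed at every grid node of the window, the null distribution of the
#' field maximum `max |t|` is built by re-assigning group labels, and the
#' `1 - alpha` quantile of that distribution is the family-wise critical
#' threshold. Contiguous supra-threshold runs are the significant clusters.
#'
#' @param groupA,groupB trajectory matrices (strides by percent) on a
#'   common grid. Nodes with any non-finite value inside the window are
#'   dropped (stance-window metrics end at slightly different percents).
#' @param window `c(start, end)` in percent (default: whole grid).
#' @param alpha family-wise significance level (default 0.05).
#' @param nperm number of permutations (default 10000; exhaustive
#'   enumeration is used instead when it is cheaper).
#' @param percent_grid node positions in percent.
#' @return object of class `spm_result`: list with `percent` (analysed
#'   nodes), `t` (t-field), `crit` (permutation threshold), `clusters`
#'   (data.frame `start`,`end` in percent), `significant`, `alpha`,
#'   `nperm`, `n` (group sizes).
#' @export
spm_compare <- function(groupA, groupB, window = NULL, alpha = 0.05,
                        nperm = 10000L,
                        percent_grid = seq(0, 100, length.out = ncol(groupA))) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            ncol(groupA) == ncol(groupB))
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 5L || nB < 5L)
    stop("spm_compare: need at least 5 trajectories per group", call. = FALSE)
  if (is.null(window)) window <- range(percent_grid)
  in_win <- percent_grid >= window[1] - 1e-9 & percent_grid <= window[2] + 1e-9
  X <- rbind(groupA, groupB)[, in_win, drop = FALSE]
  keep <- colSums(!is.finite(X)) == 0L
  X <- X[, keep, drop = FALSE]
  pct <- percent_grid[in_win][keep]
  p <- ncol(X)
  if (p < 2L)
    stop("spm_compare: no common finite support inside the window", call. = FALSE)
  n <- nA + nB

  tfield <- function(isA) {
    a <- X[isA, , drop = FALSE]; b <- X[!isA, , drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colSums(a * a) - nA * ma^2
    vb <- colSums(b * b) - nB * mb^2
    sp2 <- (va + vb) / (n - 2L)
    (ma - mb) / sqrt(sp2 * (1 / nA + 1 / nB))
  }
  obs_lab <- c(rep(TRUE, nA), rep(FALSE, nB))
  t_obs <- tfield(obs_lab)
  if (all(!is.finite(t_obs)))
    stop("spm_compare: degenerate variance, no test possible", call. = FALSE)

  n_exhaustive <- choose(n, nA)
  if (n_exhaustive <= nperm) {
    combs <- utils::combn(n, nA)
    labs <- matrix(FALSE, ncol(combs), n)
    labs[cbind(rep(seq_len(ncol(combs)), each = nA), as.vector(combs))] <- TRUE
    nperm_used <- ncol(combs)
  } else {
    labs <- t(replicate(nperm - 1L, {
      v <- rep(FALSE, n); v[sample.int(n, nA)] <- TRUE; v
    }))
    labs <- rbind(matrix(obs_lab, 1L), labs)  # observed labelling included
    nperm_used <- nperm
  }
  # vectorized permutation t-fields via matrix products
  S1 <- colSums(X); S2 <- colSums(X * X)
  L <- 1 * labs                                  # nperm x n indicator
  SA <- L %*% X                                  # group-A sums
  SA2 <- L %*% (X * X)
  MA <- SA / nA
  MB <- sweep(-SA, 2L, S1, `+`) / nB
  VA <- SA2 - nA * MA^2
  VB <- sweep(-SA2, 2L, S2, `+`) - nB * MB^2
  SP2 <- (VA + VB) / (n - 2L)
  Tm <- (MA - MB) / sqrt(SP2 * (1 / nA + 1 / nB))
  maxT <- apply(abs(Tm), 1L, max, na.rm = TRUE)
  crit <- sort(maxT)[ceiling((1 - alpha) * nperm_used)]

  above <- is.finite(t_obs) & abs(t_obs) > crit
  clusters <- data.frame(start = numeric(0), end = numeric(0))
  if (any(above)) {
    r <- rle(above)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    w <- which(r$values)
    clusters <- data.frame(start = pct[s[w]], end = pct[e[w]])
  }
  structure(list(percent = pct, t = t_obs, crit = crit, clusters = clusters,
                 significant = nrow(clusters) > 0L, alpha = alpha,
                 nperm = nperm_used, n = c(nA = nA, nB = nB),
                 window = window),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> window [%.0f, %.0f]%%, max|t| %.2f vs crit %.2f (alpha %.2f, %d perms): %s\n",
              x$window[1], x$window[2], max(abs(x$t)), x$crit, x$alpha,
              x$nperm, if (x$significant) "significant" else "not significant"))
  if (nrow(x$clusters))
    cat("  clusters:", paste(sprintf("[%.0f, %.0f]%%", x$clusters$start,
                                     x$clusters$end), collapse = ", "), "\n")
  invisible(x)
}

#' Merge disturbance conditions that SPM cannot distinguish
#'
#' The twelve conditions live in four type-by-timing cells (three
#' intensities each). Pairwise SPM comparisons are intensity-matched; two
#' cells merge when the majority of their intensity-matched comparisons are
#' non-significant, and the final partition is the transitive closure
#' (connected components) of the merge relation. Intensities are never a
#' splitting factor: they are the ordinal outcome.
#'
#' @param comparisons data.frame with columns `cell_a`, `cell_b` (cell
#'   labels such as "flexion.IDS"), `intensity`, `significant` (logical).
#' @return list with `partition` (named integer vector, cell -> group id),
#'   `groups` (list of cell-label vectors) and `cell_decisions` (data.frame
#'   of per-cell-pair merge decisions).
#' @export
merge_conditions <- function(comparisons) {
  stopifnot(all(c("cell_a", "cell_b", "significant") %in% names(comparisons)))
  cells <- sort(unique(c(comparisons$cell_a, comparisons$cell_b)))
  key <- paste(pmin(comparisons$cell_a, comparisons$cell_b),
               pmax(comparisons$cell_a, comparisons$cell_b), sep = "|")
  dec <- do.call(rbind, lapply(split(comparisons, key), function(d) {
    data.frame(cell_a = pmin(d$cell_a[1], d$cell_b[1]),
               cell_b = pmax(d$cell_a[1], d$cell_b[1]),
               n_comparisons = nrow(d),
               n_significant = sum(d$significant),
               merge = sum(!d$significant) > nrow(d) / 2)
  }))
  rownames(dec) <- NULL
  # union-find over cells
  parent <- stats::setNames(seq_along(cells), cells)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(dec))) {
    if (!dec$merge[k]) next
    ra <- find(match(dec$cell_a[k], cells))
    rb <- find(match(dec$cell_b[k], cells))
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(cells), find, integer(1))
  gid <- as.integer(factor(roots, levels = unique(roots)))
  partition <- stats::setNames(gid, cells)
  groups <- split(cells, gid)
  names(groups) <- vapply(groups, function(g) {
    types <- unique(sub("\\..*$", "", g))
    if (length(types) == 1L) types else paste(g, collapse = "+")
  }, character(1))
  list(partition = partition, groups = groups, cell_decisions = dec)
}
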