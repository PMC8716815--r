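#' Bray-Curtis dissimilarity between samples
#'
#' `d(j, k) = 1 - 2 * sum(min(x_j, x_k)) / (sum(x_j) + sum(x_k))` computed
#' on the count columns of an abundance table.
#'
#' @param x an `abundance_table` (or a samples-in-columns count matrix).
#' @return a `dist` object with sample labels; entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  counts <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop_endo("zero-total sample(s): %s",
              paste(colnames(counts)[totals == 0], collapse = ", "),
              class = "validation_error")
  vegan::vegdist(t(counts), method = "bray")
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) as.matrix(d)
  else if (is.matrix(d)) d
  else stop_endo("expected a dist object or matrix", class = "validation_error")
}

check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop_endo("need at least two groups", class = "validation_error")
  if (any(sizes < 2L))
    stop_endo("every group needs at least two samples",
              class = "validation_error")
  groups
}

# within-group sum of squared distances / group size, summed over groups
permanova_ssw <- function(D2, idx_by_group) {
  s <- 0
  for (idx in idx_by_group)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  s
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the squared dissimilarities into between- and within-group
#' components and tests the pseudo-F statistic by random permutation of the
#' group labels: `p = (1 + #permuted F >= observed F) / (n_perm + 1)`.
#'
#' @param d distances (`dist` or symmetric matrix).
#' @param groups group label per sample; >= 2 groups of >= 2 samples.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return a `permutation_test` object with `statistic` (pseudo-F), `r2`,
#'   `p`, `df`, `n_perm` and `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- as_dist_matrix(d)
  n <- nrow(D)
  groups <- check_groups(groups, n)
  D2 <- D^2
  g <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  stat_fun <- function(lab) {
    ssw <- permanova_ssw(D2, split(seq_len(n), lab))
    ssb <- ss_total - ssw
    (ssb / (g - 1)) / (ssw / (n - g))
  }
  f_obs <- stat_fun(groups)
  ssw_obs <- permanova_ssw(D2, split(seq_len(n), groups))
  r2 <- (ss_total - ssw_obs) / ss_total
  p <- with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm),
                     function(i) stat_fun(sample(groups)), numeric(1))
    (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  })
  structure(list(method = "PerMANOVA", statistic = f_obs, r2 = r2, p = p,
                 df = c(g - 1L, n - g), n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' ANOSIM on a distance matrix
#'
#' Rank-based analysis of similarities:
#' `R = (mean rank between groups - mean rank within groups) / (M / 2)`
#' with `M = N (N - 1) / 2`, tested by label permutation. Tied distances
#' get average ranks.
#'
#' @inheritParams permanova
#' @return a `permutation_test` object with `statistic` (ANOSIM R in
#'   `[-1, 1]`), `p`, `n_perm` and `seed`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- as_dist_matrix(d)
  n <- nrow(D)
  groups <- check_groups(groups, n)
  pair <- which(upper.tri(D), arr.ind = TRUE)
  r <- rank(D[upper.tri(D)])
  M <- length(r)
  stat_fun <- function(lab) {
    within <- lab[pair[, 1]] == lab[pair[, 2]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  r_obs <- stat_fun(groups)
  p <- with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm),
                     function(i) stat_fun(sample(groups)), numeric(1))
    (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  })
  structure(list(method = "ANOSIM", statistic = r_obs, r2 = NA_real_, p = p,
                 df = NULL, n_perm = n_perm, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g (%d permutations)\n",
              x$method, x$statistic,
              if (!is.na(x$r2)) sprintf(", R2 = %.4f", x$r2) else "",
              x$p, x$n_perm))
  invisible(x)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS with multiple random starts, as implemented by
#' `vegan::metaMDS` (the field-standard engine); coordinates and the final
#' stress are returned, reproducibly for a given seed.
#'
#' @param d distances (`dist` or symmetric matrix).
#' @param k number of ordination dimensions.
#' @param n_starts number of random starts.
#' @param seed integer seed.
#' @param max_iter maximum iterations per start.
#' @return an `nmds_fit`: list with `points` (samples x k), `stress`
#'   (stress-1, as a proportion in `[0, 1]`) and `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = NULL, max_iter = 200) {
  if (!inherits(d, "dist")) d <- as.dist(as_dist_matrix(d))
  n <- attr(d, "Size")
  if (n < k + 2)
    stop_endo("NMDS with k = %d needs at least %d samples", k, k + 2,
              class = "validation_error")
  fit <- with_seed(seed, {
    suppressWarnings(vegan::metaMDS(d, k = k, try = n_starts,
                                    trymax = max(n_starts, 20),
                                    maxit = max_iter, trace = 0,
                                    autotransform = FALSE, wascores = FALSE))
  })
  if (!isTRUE(fit$converged))
    warning("NMDS did not converge; returning the best solution found")
  structure(list(points = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged), k = k, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f%s\n", x$k, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(as.factor(groups))
  plot(x$points[, 1], x$points[, 2], col = col, pch = 19,
       xlab = "NMDS1", ylab = "NMDS2",
       main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}
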