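#' Raup-Crick index of pairwise compositional stochasticity
#'
#' For each pair of samples the observed number of shared taxa is compared
#' with a null distribution obtained by drawing, `n_reps` times, two random
#' communities of the observed richnesses from the regional taxon pool
#' (all taxa of the table passed in). Draws are without replacement, with
#' selection probability proportional to each taxon's occurrence frequency
#' when `weighted = TRUE` and uniform otherwise. The index is
#' `RCI = 2 * (#null < obs + 0.5 * #null == obs) / n_reps - 1`, in
#' `[-1, 1]`; values near 0 indicate sharing indistinguishable from the
#' null (stochastic assembly), values near +/-1 indicate more/less sharing
#' than expected.
#'
#' @param x an `abundance_table` (reduced to presence/absence internally)
#'   or a taxa-by-samples matrix. All taxa of the table form the pool;
#'   under the weighted null, taxa never observed have zero weight.
#' @param n_reps null replicates per pair.
#' @param weighted weight null draws by occurrence frequency.
#' @param seed integer seed.
#' @return an object of class `raup_crick`: `rci` (symmetric matrix, `NA`
#'   diagonal), `labels`, `n_reps`, `weighted`, `seed`.
#' @export
raup_crick <- function(x, n_reps = 999, weighted = TRUE, seed = NULL) {
  counts <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  if (ncol(counts) < 2L)
    stop_endo("need at least two samples", class = "validation_error")
  inc <- counts > 0
  S <- nrow(inc)
  occ <- rowSums(inc)
  w <- if (weighted) occ else rep(1, S)
  pool_size <- sum(w > 0)
  richness <- colSums(inc)
  if (any(richness > pool_size))
    stop_endo("sample richness exceeds the size of the (weighted) pool",
              class = "validation_error")
  n <- ncol(inc)
  rci <- matrix(NA_real_, n, n, dimnames = list(colnames(counts),
                                                colnames(counts)))
  zero <- richness == 0
  if (any(zero))
    warning(sprintf("skipping pairs with empty sample(s): %s",
                    paste(colnames(counts)[zero], collapse = ", ")))
  with_seed(seed, {
    # two independent null ensembles of weighted orderings (one per member
    # of a pair); taxon i belongs to a null community of richness r in
    # replicate b iff its key rank is <= r (Efraimidis-Spirakis weighted
    # sampling without replacement)
    rnk_a <- rc_rank_ensemble(w, n_reps)
    rnk_b <- rc_rank_ensemble(w, n_reps)
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (zero[j] || zero[k]) next
        ss_obs <- sum(inc[, j] & inc[, k])
        ss_null <- colSums(rnk_a <= richness[j] & rnk_b <= richness[k])
        val <- 2 * (sum(ss_null < ss_obs) + 0.5 * sum(ss_null == ss_obs)) /
          n_reps - 1
        rci[j, k] <- rci[k, j] <- val
      }
    }
  })
  structure(list(rci = rci, labels = colnames(counts), n_reps = n_reps,
                 weighted = weighted, seed = seed),
            class = "raup_crick")
}

# per-replicate weighted-sampling ranks: entry [i, b] is the position of
# taxon i in replicate b's weighted without-replacement ordering; taxa with
# zero weight rank last (never drawn for any feasible richness)
rc_rank_ensemble <- function(w, n_reps) {
  S <- length(w)
  keys <- matrix(Inf, S, n_reps)
  pos <- w > 0
  keys[pos, ] <- rexp(sum(pos) * n_reps) / w[pos]
  apply(keys, 2, rank, ties.method = "first")
}

#' @export
print.raup_crick <- function(x, ...) {
  vals <- x$rci[upper.tri(x$rci)]
  cat(sprintf("Raup-Crick: %d samples, %d pairs, %d null reps (%s null)\n",
              length(x$labels), sum(!is.na(vals)), x$n_reps,
              if (x$weighted) "occurrence-weighted" else "uniform"))
  cat(sprintf("  |RCI| < 0.95 in %.1f%% of pairs\n",
              100 * mean(abs(vals[!is.na(vals)]) < 0.95)))
  invisible(x)
}

#' Fraction of sample pairs consistent with stochastic assembly
#'
#' The proportion of (optionally within-group) pairs whose Raup-Crick
#' index satisfies `|RCI| < threshold`.
#'
#' @param result a `raup_crick` object.
#' @param threshold stochasticity threshold, in (0, 1].
#' @param groups optional group label per sample; only pairs within the
#'   same group are counted.
#' @return a single number in `[0, 1]`.
#' @export
stochastic_fraction <- function(result, threshold = 0.95, groups = NULL) {
  stopifnot(inherits(result, "raup_crick"),
            threshold > 0, threshold <= 1)
  m <- result$rci
  use <- upper.tri(m)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(m))
    same <- outer(groups, groups, "==")
    use <- use & same
  }
  vals <- m[use]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop_endo("no valid sample pairs for the requested grouping",
              class = "validation_error")
  mean(abs(vals) < threshold)
}
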