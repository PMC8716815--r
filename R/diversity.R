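#' Hill number of a single community
#'
#' Effective number of equally-abundant taxa of order `q`: `q = 0` is
#' richness, `q = 1` the exponential of Shannon entropy (natural log) and
#' `q = 2` the inverse Simpson concentration `1 / sum(p_i^2)`.
#'
#' @param abundances non-negative abundance (or incidence) vector with at
#'   least one positive entry.
#' @param q diversity order (non-negative real; 0, 1 and 2 are the
#'   conventional choices).
#' @return the Hill number, a number >= 1 for any non-empty community.
#' @examples
#' hill_number(c(0.5, 0.5), 1)  # 2: two equally common taxa
#' hill_number(c(0.9, 0.1), 2)  # 1/0.82
#' @export
hill_number <- function(abundances, q) {
  stopifnot(is.numeric(abundances), length(q) == 1L, q >= 0)
  if (anyNA(abundances) || any(abundances < 0))
    stop_endo("abundances must be non-negative", class = "validation_error")
  x <- abundances[abundances > 0]
  if (!length(x))
    stop_endo("all-zero community", class = "validation_error")
  p <- x / sum(x)
  if (q == 0) return(length(p))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# plug-in incidence Hill number from an incidence-frequency vector y
# (number of units each taxon occurs in); relative incidences y/sum(y)
incidence_hill <- function(y, q) {
  y <- y[y > 0]
  if (!length(y)) return(0)
  if (q == 0) return(length(y))
  hill_number(y, q)
}

# closed-form interpolated richness at t of T units: the hypergeometric
# expectation of the number of taxa detected in a random subset of t units
interp_richness <- function(y, T_units, t) {
  lt <- lchoose(T_units, t)
  sum(1 - exp(lchoose(T_units - y, t) - lt))
}

# expectation of the plug-in Hill number over random t-subsets of units:
# exact enumeration when the number of subsets is small, Monte Carlo
# otherwise (q = 0 always uses the closed form). Subsets are evaluated in
# one shot as an incidence x indicator matrix product.
interp_hill <- function(inc, q, t, max_subsets = 20000L, n_draws = 200L) {
  T_units <- ncol(inc)
  y <- rowSums(inc)
  if (q == 0) return(interp_richness(y, T_units, t))
  n_sub <- choose(T_units, t)
  Z <- if (n_sub <= max_subsets) {
    subsets <- utils::combn(T_units, t)
    z <- matrix(0, T_units, ncol(subsets))
    z[cbind(as.vector(subsets),
            rep(seq_len(ncol(subsets)), each = t))] <- 1
    z
  } else {
    z <- matrix(0, T_units, n_draws)
    for (b in seq_len(n_draws)) z[sample.int(T_units, t), b] <- 1
    z
  }
  Y <- inc %*% Z                     # taxa x subsets incidence counts
  U <- colSums(Y)
  P <- sweep(Y, 2, U, "/")
  vals <- if (abs(q - 1) < 1e-12) {
    PL <- P * log(P)
    PL[Y == 0] <- 0
    exp(-colSums(PL))
  } else {
    colSums(P^q)^(1 / (1 - q))
  }
  mean(vals[U > 0])
}

# Chao2 estimate of undetected taxa from incidence frequency counts
chao2_q0 <- function(Q1, Q2, T_units) {
  k <- (T_units - 1) / T_units
  if (Q2 > 0) k * Q1^2 / (2 * Q2) else k * Q1 * (Q1 - 1) / 2
}

# asymptotic incidence diversity estimates used as extrapolation targets
asymptote_hill <- function(y, T_units, q) {
  U <- sum(y)
  if (q == 0) {
    Q1 <- sum(y == 1); Q2 <- sum(y == 2)
    return(length(y) + chao2_q0(Q1, Q2, T_units))
  }
  if (q == 2) {
    s2 <- sum(y * (y - 1))
    if (s2 == 0) return(length(y))
    return(U^2 * (T_units - 1) / (T_units * s2))
  }
  # q = 1: coverage-adjusted (Chao-Shen style) incidence entropy
  Q1 <- sum(y == 1)
  C_hat <- if (U > 0) 1 - Q1 / U else 1
  if (C_hat <= 0) C_hat <- 1 / U
  pi_hat <- C_hat * y / U
  w <- 1 - (1 - pi_hat)^T_units
  exp(-sum(pi_hat * log(pi_hat) / w))
}

hill_curve_point <- function(inc, q, t, max_subsets, n_draws) {
  T_units <- ncol(inc)
  y <- rowSums(inc)
  y <- y[y > 0]
  obs <- incidence_hill(y, q)
  if (t == T_units) {
    c(estimate = obs, method = 1)
  } else if (t < T_units) {
    c(estimate = interp_hill(inc, q, t, max_subsets, n_draws), method = 0)
  } else {
    Q1 <- sum(y == 1); Q2 <- sum(y == 2)
    Q0 <- chao2_q0(Q1, Q2, T_units)
    m <- t - T_units
    if (q == 0) {
      est <- if (Q1 == 0 || Q0 == 0) obs else
        obs + Q0 * (1 - (1 - Q1 / (Q1 + T_units * Q0))^m)
    } else {
      asy <- max(asymptote_hill(y, T_units, q), obs)
      g <- if (Q1 == 0 || Q0 == 0) 1 else Q1 / (Q1 + T_units * Q0)
      est <- obs + (asy - obs) * (1 - (1 - g)^m)
    }
    c(estimate = est, method = 2)
  }
}

#' Sample-size-based rarefaction and extrapolation of incidence diversity
#'
#' Builds the diversity curve of Hill order `q` for incidence data over a
#' range of numbers of sampling units. Interpolated values are the
#' expectation of the empirical diversity over random subsets of units
#' (closed form for `q = 0`, exact subset enumeration or Monte Carlo
#' otherwise); the curve passes through the empirical value at the observed
#' size; extrapolation uses the Chao2 estimate of undetected taxa for
#' `q = 0` and approaches the asymptotic incidence estimators for
#' `q = 1, 2`. Confidence bands come from bootstrap resampling of units.
#'
#' @param incidence presence/absence matrix (taxa x sampling units); counts
#'   are accepted and reduced to incidence.
#' @param q Hill order (0, 1 or 2).
#' @param sizes integer unit counts at which to evaluate the curve; default
#'   `1 .. 2 * T` where `T` is the observed number of units. Sizes beyond
#'   `2 * T` trigger a warning.
#' @param n_boot bootstrap replicates for the confidence band (0 disables).
#' @param conf confidence level of the band.
#' @param seed integer seed.
#' @param max_subsets enumerate subsets exactly when `choose(T, t)` is at
#'   most this; otherwise use `n_draws` Monte-Carlo subsets.
#' @param n_draws Monte-Carlo subsets for large interpolation problems.
#' @return data.frame with columns `q`, `size`, `method`
#'   (interpolated/observed/extrapolated), `estimate`, `lower`, `upper`.
#' @export
hill_curve <- function(incidence, q = 0, sizes = NULL, n_boot = 200,
                       conf = 0.95, seed = NULL, max_subsets = 20000L,
                       n_draws = 200L) {
  inc <- (as.matrix(incidence) > 0) * 1L
  T_units <- ncol(inc)
  stopifnot(T_units >= 1L, q %in% c(0, 1, 2))
  if (is.null(sizes)) sizes <- seq_len(2L * T_units)
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(all(sizes >= 1L))
  if (any(sizes > T_units) && T_units < 2L)
    stop_endo("extrapolation needs at least 2 sampling units",
              class = "validation_error")
  if (any(sizes > 2L * T_units))
    warning("extrapolating beyond twice the observed number of units")

  with_seed(seed, {
    pts <- vapply(sizes, function(t)
      hill_curve_point(inc, q, t, max_subsets, n_draws), numeric(2))
    est <- pts["estimate", ]
    method <- c("interpolated", "observed", "extrapolated")[pts["method", ] + 1]
    lower <- upper <- rep(NA_real_, length(sizes))
    if (n_boot > 0) {
      boot <- matrix(NA_real_, n_boot, length(sizes))
      for (b in seq_len(n_boot)) {
        bi <- inc[, sample.int(T_units, T_units, replace = TRUE), drop = FALSE]
        if (all(bi == 0)) next
        boot[b, ] <- vapply(sizes, function(t)
          hill_curve_point(bi, q, t, max_subsets, n_draws)[1], numeric(1))
      }
      a <- (1 - conf) / 2
      lower <- apply(boot, 2, quantile, probs = a, na.rm = TRUE)
      upper <- apply(boot, 2, quantile, probs = 1 - a, na.rm = TRUE)
    }
    data.frame(q = q, size = sizes, method = method, estimate = est,
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  })
}
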