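#' Occupancy predicted by the Sloan neutral community model
#'
#' Under the neutral model, the local relative abundance of a taxon with
#' metacommunity relative abundance `p` follows a Beta distribution with
#' parameters `Nm * p` and `Nm * (1 - p)`, where `Nm` is the product of
#' local community size and immigration rate. The expected occupancy is the
#' probability that the local abundance exceeds the detection limit `d`
#' (1 / sequencing depth after rarefaction):
#' `1 - pbeta(d, Nm * p, Nm * (1 - p))`.
#'
#' @param p metacommunity relative abundance(s), strictly in (0, 1).
#' @param Nm positive real; dispersal parameter of the model.
#' @param d detection limit, in (0, 1).
#' @return predicted occupancy in `[0, 1]`, vectorised over `p`.
#' @export
ncm_predicted_freq <- function(p, Nm, d) {
  stopifnot(length(Nm) == 1L, Nm > 0, length(d) == 1L, d > 0, d < 1)
  if (any(p <= 0 | p >= 1))
    stop_endo("p must be strictly inside (0, 1)", class = "validation_error")
  pbeta(d, Nm * p, Nm * (1 - p), lower.tail = FALSE)
}

# least-squares fit of log(Nm); bounded scalar search with multistart
fit_nm_scalar <- function(p, freq, d, lower = log(1), upper = log(1e7),
                          n_start = 5L) {
  sse <- function(lnm) sum((freq - ncm_predicted_freq(p, exp(lnm), d))^2)
  cuts <- seq(lower, upper, length.out = n_start + 1L)
  best <- NULL
  for (i in seq_len(n_start)) {
    o <- optimize(sse, c(cuts[i], cuts[i + 1L]), tol = 1e-8)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (!is.finite(best$objective))
    stop_endo("neutral-model optimisation failed (non-finite SSE)",
              class = "fit_error")
  list(Nm = exp(best$minimum), sse = best$objective)
}

#' Fit the Sloan neutral community model
#'
#' Estimates `Nm` by nonlinear least squares of observed taxon occupancy on
#' the occupancy predicted from mean relative abundance (detection limit
#' `d = 1 / depth`), computes a generalised R-squared
#' (`1 - SSE / SST`, SST about the mean observed occupancy; can be negative),
#' classifies each taxon against a 95% Wilson score band around its
#' predicted occupancy at the observed number of samples (`above` /
#' `neutral` / `below`), and bootstraps `Nm` and R-squared confidence
#' intervals by resampling taxa.
#'
#' @param x a `taxon_stats` object (see [taxon_stats()]) or an
#'   `abundance_table` (stats are computed, and `depth` defaults to the
#'   common sample sum when the table is evenly rarefied).
#' @param depth sequencing depth after rarefaction; sets `d = 1 / depth`.
#' @param n_boot bootstrap replicates for the confidence intervals
#'   (0 disables bootstrapping).
#' @param conf confidence level for the bootstrap intervals and the
#'   per-taxon binomial band.
#' @param seed integer seed for the bootstrap.
#' @return an object of class `ncm_fit`; see Details. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @details The fitted object carries `Nm`, `r2`, `d`, `n_samples`, the
#'   per-taxon table `taxa` (taxon, p, freq, freq_hat, ci_lower, ci_upper,
#'   label) and bootstrap intervals `Nm_ci`, `r2_ci`. Taxa with `p` equal
#'   to 0 or 1 cannot enter the beta prediction and are excluded from the
#'   fit (none remain after standard preprocessing of an evenly rarefied
#'   table with at least one shared taxon).
#' @export
fit_ncm <- function(x, depth = NULL, n_boot = 1000, conf = 0.95,
                    seed = NULL) {
  if (inherits(x, "abundance_table")) {
    if (is.null(depth)) {
      totals <- unique(colSums(x$counts))
      if (length(totals) != 1L)
        stop_endo("depth must be given for unevenly sampled tables",
                  class = "validation_error")
      depth <- totals
    }
    x <- taxon_stats(x)
  }
  stopifnot(inherits(x, "taxon_stats"), !is.null(depth), depth >= 1)
  d <- 1 / depth
  ok <- x$p > 0 & x$p < 1
  if (sum(ok) < 10L)
    stop_endo("need at least 10 taxa with 0 < p < 1 (have %d)", sum(ok),
              class = "validation_error")
  p <- x$p[ok]; freq <- x$freq[ok]; ids <- x$taxon_id[ok]
  S <- x$n_samples

  fit <- fit_nm_scalar(p, freq, d)
  freq_hat <- ncm_predicted_freq(p, fit$Nm, d)
  sst <- sum((freq - mean(freq))^2)
  r2 <- if (sst > 0) 1 - fit$sse / sst else NA_real_

  band <- wilson_interval(freq_hat, S, conf)
  label <- ifelse(freq > band[, "upper"], "above",
                  ifelse(freq < band[, "lower"], "below", "neutral"))

  Nm_ci <- r2_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(length(p), replace = TRUE)
        # the SSE profile is unimodal in log(Nm); a single bounded search
        # suffices for the bootstrap refits
        bf <- fit_nm_scalar(p[i], freq[i], d, n_start = 1L)
        bsst <- sum((freq[i] - mean(freq[i]))^2)
        c(bf$Nm, if (bsst > 0) 1 - bf$sse / bsst else NA_real_)
      }, numeric(2))
    })
    a <- (1 - conf) / 2
    Nm_ci <- unname(quantile(boots[1, ], c(a, 1 - a), na.rm = TRUE))
    r2_ci <- unname(quantile(boots[2, ], c(a, 1 - a), na.rm = TRUE))
  }

  structure(list(
    Nm = fit$Nm, r2 = r2, d = d, n_samples = S, sse = fit$sse,
    Nm_ci = Nm_ci, r2_ci = r2_ci, n_boot = n_boot, conf = conf, seed = seed,
    taxa = data.frame(taxon = ids, p = p, freq = freq, freq_hat = freq_hat,
                      ci_lower = band[, "lower"], ci_upper = band[, "upper"],
                      label = label, stringsAsFactors = FALSE)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model fit (%d taxa, %d samples)\n",
              nrow(x$taxa), x$n_samples))
  cat(sprintf("  Nm = %.1f", x$Nm))
  if (!anyNA(x$Nm_ci))
    cat(sprintf(" [%.1f, %.1f]", x$Nm_ci[1], x$Nm_ci[2]))
  cat(sprintf(", R2 = %.4f", x$r2))
  if (!anyNA(x$r2_ci))
    cat(sprintf(" [%.4f, %.4f]", x$r2_ci[1], x$r2_ci[2]))
  cat(sprintf(", detection limit d = %.3g\n", x$d))
  invisible(x)
}

#' @export
summary.ncm_fit <- function(object, ...) {
  lab <- factor(object$taxa$label, levels = c("below", "neutral", "above"))
  out <- list(Nm = object$Nm, Nm_ci = object$Nm_ci, r2 = object$r2,
              r2_ci = object$r2_ci, d = object$d,
              n_taxa = nrow(object$taxa), n_samples = object$n_samples,
              label_counts = table(lab))
  class(out) <- "summary.ncm_fit"
  out
}

#' @export
print.summary.ncm_fit <- function(x, ...) {
  cat(sprintf("Neutral model: Nm = %.1f, R2 = %.4f, d = %.3g\n",
              x$Nm, x$r2, x$d))
  cat(sprintf("%d taxa over %d samples; deviation labels:\n",
              x$n_taxa, x$n_samples))
  print(x$label_counts)
  invisible(x)
}

#' @export
coef.ncm_fit <- function(object, ...) c(Nm = object$Nm)

#' @export
fitted.ncm_fit <- function(object, ...) {
  structure(object$taxa$freq_hat, names = object$taxa$taxon)
}

#' @export
residuals.ncm_fit <- function(object, ...) {
  structure(object$taxa$freq - object$taxa$freq_hat,
            names = object$taxa$taxon)
}

#' Predicted occupancy from a fitted neutral model
#'
#' @param object an `ncm_fit`.
#' @param newdata optional vector of metacommunity relative abundances;
#'   defaults to the abundances used in the fit.
#' @param ... ignored.
#' @export
predict.ncm_fit <- function(object, newdata = NULL, ...) {
  p <- newdata %||% object$taxa$p
  ncm_predicted_freq(p, object$Nm, object$d)
}

#' Occupancy-abundance plot of a neutral model fit
#'
#' @param x an `ncm_fit`.
#' @param ... passed to `plot`.
#' @export
plot.ncm_fit <- function(x, ...) {
  cols <- c(above = "#d95f02", neutral = "grey40", below = "#7570b3")
  with(x$taxa, {
    plot(p, freq, log = "x", pch = 19, cex = 0.6, col = cols[label],
         xlab = "mean relative abundance", ylab = "occupancy",
         main = sprintf("Sloan NCM: Nm = %.0f, R2 = %.3f", x$Nm, x$r2), ...)
    o <- order(p)
    lines(p[o], freq_hat[o], lwd = 2)
    lines(p[o], ci_lower[o], lty = 2)
    lines(p[o], ci_upper[o], lty = 2)
  })
  invisible(x)
}

#' Cross-season persistence of neutral-model deviations
#'
#' Given one fitted neutral model per season, records, per taxon and
#' deviation direction, the set and number of seasons in which the taxon
#' deviates from the neutral prediction. Taxa absent from a season's fit
#' count as non-deviating in that season.
#'
#' @param fits named list of `ncm_fit` objects (names are season labels;
#'   2-4 seasons, no duplicates).
#' @param min_count records with at least this many deviating seasons are
#'   flagged `persistent`.
#' @return data.frame with columns `taxon`, `direction`, `seasons`
#'   (comma-separated), `count` and `persistent`.
#' @export
persistence_across_seasons <- function(fits, min_count = 4) {
  stopifnot(is.list(fits), length(fits) >= 2L, length(fits) <= 4L)
  if (is.null(names(fits)) || anyDuplicated(names(fits)) || any(names(fits) == ""))
    stop_endo("fits must be uniquely named by season", class = "validation_error")
  recs <- list()
  for (season in names(fits)) {
    f <- fits[[season]]
    stopifnot(inherits(f, "ncm_fit"))
    dev <- f$taxa[f$taxa$label != "neutral", c("taxon", "label")]
    if (nrow(dev))
      recs[[season]] <- data.frame(season = season, taxon = dev$taxon,
                                   direction = dev$label,
                                   stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(taxon = character(), direction = character(),
                      seasons = character(), count = integer(),
                      persistent = logical(), stringsAsFactors = FALSE))
  all <- do.call(rbind, recs)
  key <- paste(all$taxon, all$direction, sep = "\r")
  agg <- lapply(split(all, key), function(g)
    data.frame(taxon = g$taxon[1], direction = g$direction[1],
               seasons = paste(sort(g$season), collapse = ","),
               count = nrow(g), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out$persistent <- out$count >= min_count
  out[order(-out$count, out$taxon), ]
}
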