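# synthetic multi-season community generator: a neutral
# Dirichlet-multinomial backbone with planted non-neutral taxa and planted
# season-persistent correlated pairs

#' Describe a synthetic multi-season study design
#'
#' Captures the generator parameters for a study laid out like a
#' two-site, two-tissue, four-season, five-replicate sampling campaign
#' rarefied to a common depth. The neutral backbone draws each sample's
#' composition from a Dirichlet with concentration `Nm * pool` and counts
#' from a multinomial at `depth` -- the exact finite-sample counterpart of
#' the Sloan beta approximation, so the generator and the neutral-model
#' estimator are internally consistent.
#'
#' Planted signals provide ground truth for the downstream detectors:
#' `selected` taxa (rare, forced present in every sample -> occupancy above
#' the neutral prediction), `limited` taxa (zeroed in a fraction of
#' samples -> occupancy below prediction), and correlated taxon pairs
#' active in a chosen subset of seasons. Pair taxa are seasonal
#' specialists: elevated pool abundance in their active seasons and
#' essentially absent otherwise, as transient seasonal associations are in
#' real communities.
#'
#' @param n_taxa number of background taxa in the regional pool.
#' @param pool pool abundance distribution: `"lognormal"` or `"geometric"`.
#' @param pool_sdlog lognormal sd (log scale) of the pool.
#' @param Nm dispersal parameter of the neutral backbone.
#' @param sites,tissues,seasons design factor levels.
#' @param replicates samples per site x tissue x season cell.
#' @param depth reads per sample.
#' @param n_selected,selected_abundance number and pool relative abundance
#'   range of planted host-selected taxa.
#' @param n_limited,limited_abundance,limited_zero_fraction planted
#'   dispersal-limited taxa: count, abundance range, and the fraction of
#'   samples zeroed per slice.
#' @param pairs data.frame describing planted correlated pairs (columns
#'   `sign` in positive/negative and `seasons`, a comma-separated subset of
#'   `seasons`), or `NULL` for the default set (three two-season pairs, one
#'   three-season pair, two single-season pairs).
#' @param pair_abundance pool relative abundance of pair taxa in their
#'   active seasons.
#' @param season_drift sd (log scale) of the multiplicative pool drift
#'   between consecutive seasons.
#' @param group_effect sd (log scale) of a fixed multiplicative pool
#'   perturbation per site x tissue group.
#' @param seed integer seed used by [generate_study()].
#' @return an object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_taxa = 400,
                             pool = c("lognormal", "geometric"),
                             pool_sdlog = 0.8,
                             Nm = 50,
                             sites = c("control", "radiation"),
                             tissues = c("aerial", "root"),
                             seasons = c("spring", "summer", "autumn",
                                         "winter"),
                             replicates = 5,
                             depth = 7500,
                             n_selected = 6,
                             selected_abundance = c(0.0015, 0.003),
                             n_limited = 6,
                             limited_abundance = c(0.03, 0.06),
                             limited_zero_fraction = 0.6,
                             pairs = NULL,
                             pair_abundance = 0.006,
                             season_drift = 0.1,
                             group_effect = 0.15,
                             seed = 1) {
  pool <- match.arg(pool)
  stopifnot(n_taxa >= 2, Nm > 0, depth >= 1, replicates >= 1,
            length(seasons) >= 1, limited_zero_fraction >= 0,
            limited_zero_fraction < 1)
  if (is.null(pairs)) {
    s <- seasons
    pairs <- data.frame(
      sign = c("positive", "negative", "positive", "positive",
               "positive", "negative"),
      seasons = c(paste(s[c(1, 2)], collapse = ","),
                  paste(s[c(2, 3)], collapse = ","),
                  paste(s[c(3, 4)], collapse = ","),
                  paste(s[c(1, 2, 3)], collapse = ","),
                  s[1], s[4]),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(pairs$sign %in% c("positive", "negative")))
  season_sets <- strsplit(pairs$seasons, ",", fixed = TRUE)
  if (any(lengths(season_sets) == 0) ||
      !all(unlist(season_sets) %in% seasons))
    stop_endo("pair season subsets must be non-empty subsets of `seasons`",
              class = "validation_error")
  n_pairs <- nrow(pairs)
  pairs$taxon_a <- sprintf("pairA_%02d", seq_len(n_pairs))
  pairs$taxon_b <- sprintf("pairB_%02d", seq_len(n_pairs))
  design <- list(
    n_taxa = n_taxa, pool = pool, pool_sdlog = pool_sdlog, Nm = Nm,
    sites = sites, tissues = tissues, seasons = seasons,
    replicates = replicates, depth = depth,
    selected_taxa = if (n_selected > 0)
      sprintf("sel_%02d", seq_len(n_selected)) else character(),
    selected_abundance = selected_abundance,
    limited_taxa = if (n_limited > 0)
      sprintf("lim_%02d", seq_len(n_limited)) else character(),
    limited_abundance = limited_abundance,
    limited_zero_fraction = limited_zero_fraction,
    pairs = pairs, pair_abundance = pair_abundance,
    season_drift = season_drift, group_effect = group_effect, seed = seed)
  overlap <- intersect(c(pairs$taxon_a, pairs$taxon_b), design$limited_taxa)
  if (length(overlap))
    stop_endo("planted pair taxa overlap limited taxa: %s",
              paste(overlap, collapse = ", "), class = "validation_error")
  class(design) <- "synthetic_design"
  design
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "synthetic_design: %d taxa, Nm = %g, %d x %d x %d x %d design, depth %d\n",
    x$n_taxa, x$Nm, length(x$sites), length(x$tissues), length(x$seasons),
    x$replicates, x$depth))
  cat(sprintf("  planted: %d selected, %d limited, %d pairs\n",
              length(x$selected_taxa), length(x$limited_taxa),
              nrow(x$pairs)))
  invisible(x)
}

planted_ids <- function(design)
  c(design$selected_taxa, design$limited_taxa,
    design$pairs$taxon_a, design$pairs$taxon_b)

#' Regional relative-abundance pool of a synthetic design
#'
#' Draws the background pool from the design's abundance distribution and
#' assigns planted taxa their configured abundances (pair taxa get a
#' placeholder; their abundance is season-specific). The vector is named by
#' taxon id and sums to one.
#'
#' @param design a `synthetic_design`.
#' @param seed optional seed (defaults to the design seed).
#' @return named relative-abundance vector.
#' @export
make_pool <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(seed, {
    bg <- switch(design$pool,
                 lognormal = rlnorm(design$n_taxa, 0, design$pool_sdlog),
                 geometric = 0.97^seq_len(design$n_taxa))
    if (any(!is.finite(bg)) || all(bg <= 0))
      stop_endo("invalid pool parameters", class = "validation_error")
    bg <- bg / sum(bg)
    names(bg) <- sprintf("t%04d", seq_len(design$n_taxa))
    pl <- planted_ids(design)
    extra <- numeric(length(pl)); names(extra) <- pl
    ns <- length(design$selected_taxa)
    if (ns) extra[design$selected_taxa] <-
        seq(design$selected_abundance[1], design$selected_abundance[2],
            length.out = ns)
    nl <- length(design$limited_taxa)
    if (nl) extra[design$limited_taxa] <-
        seq(design$limited_abundance[1], design$limited_abundance[2],
            length.out = nl)
    extra[c(design$pairs$taxon_a, design$pairs$taxon_b)] <-
      design$pair_abundance
    pool <- c(bg * (1 - sum(extra)), extra)
    pool / sum(pool)
  })
}

# per-season pools: bounded multiplicative drift between consecutive
# seasons, plus the seasonal on/off profile of the planted pair taxa
seasonal_pools <- function(design, pool) {
  out <- list()
  current <- pool
  for (si in seq_along(design$seasons)) {
    season <- design$seasons[si]
    if (si > 1 && design$season_drift > 0) {
      jitter <- rlnorm(length(current), 0, design$season_drift)
      current <- current * jitter
      current <- current / sum(current)
    }
    p <- current
    for (i in seq_len(nrow(design$pairs))) {
      active <- season %in% strsplit(design$pairs$seasons[i], ",")[[1]]
      ids <- c(design$pairs$taxon_a[i], design$pairs$taxon_b[i])
      p[ids] <- if (active) design$pair_abundance else 1e-9
    }
    out[[season]] <- p / sum(p)
  }
  out
}

#' Simulate one neutral community group
#'
#' Each sample's composition is drawn from a Dirichlet distribution with
#' concentration `Nm * p` and its counts from a multinomial at `depth`,
#' so the per-taxon marginal matches the Sloan beta approximation.
#'
#' @param p named relative-abundance pool (positive, sums to 1).
#' @param Nm dispersal parameter (> 0).
#' @param n_samples number of samples.
#' @param depth reads per sample.
#' @param seed optional seed.
#' @param sample_ids optional sample names.
#' @return an `abundance_table` (metadata holds only sample ids).
#' @export
simulate_neutral_group <- function(p, Nm, n_samples, depth, seed = NULL,
                                   sample_ids = NULL) {
  stopifnot(Nm > 0, depth >= 1, n_samples >= 1, all(p > 0))
  if (is.null(names(p))) names(p) <- sprintf("t%04d", seq_along(p))
  counts <- with_seed(seed, {
    vapply(seq_len(n_samples), function(j) {
      g <- rgamma(length(p), shape = Nm * p)
      if (sum(g) <= 0) g <- p # numerical underflow guard
      as.integer(rmultinom(1, depth, g / sum(g)))
    }, integer(length(p)))
  })
  rownames(counts) <- names(p)
  colnames(counts) <- sample_ids %||% sprintf("s%03d", seq_len(n_samples))
  abundance_table(counts)
}

# restore sample j to the target depth by adding or removing `|delta|`
# reads across the non-planted taxa, proportionally to their counts
adjust_depth <- function(counts, j, delta, protect) {
  if (delta == 0L) return(counts)
  bg <- setdiff(rownames(counts), protect)
  v <- counts[bg, j]
  if (delta > 0L) {
    add <- tabulate(sample.int(length(v), delta, replace = TRUE,
                               prob = v + 1e-9), nbins = length(v))
    counts[bg, j] <- v + as.integer(add)
  } else {
    if (sum(v) < -delta)
      stop_endo("cannot renormalise sample %s to depth",
                colnames(counts)[j], class = "validation_error")
    reads <- rep.int(seq_along(v), v)
    kept <- sample(reads, length(reads) + delta)
    counts[bg, j] <- as.integer(tabulate(kept, nbins = length(v)))
  }
  counts
}

#' Plant ground-truth signals into one seasonal slice
#'
#' Applies, in order: zeroing of `limited` taxa in a fraction of samples;
#' rewriting of each pair active in `season` as strictly monotone
#' transforms of a shared latent sample ranking (guaranteeing
#' `|rho| = 1`, sign per the design); forced presence (count >= 5) of
#' `selected` taxa in every sample; and exact renormalisation of every
#' sample to the design depth by redistributing reads proportionally
#' across the non-planted taxa.
#'
#' @param table an `abundance_table` for one site x tissue x season slice.
#' @param design a `synthetic_design`.
#' @param season the slice's season label.
#' @param seed optional seed.
#' @return the modified `abundance_table`; all sample sums equal the
#'   design depth.
#' @export
plant_signals <- function(table, design, season, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(design, "synthetic_design"))
  counts <- table$counts
  n <- ncol(counts)
  pl <- planted_ids(design)
  missing <- setdiff(pl, rownames(counts))
  if (length(missing))
    stop_endo("planted taxa absent from the table: %s",
              paste(missing, collapse = ", "), class = "validation_error")
  with_seed(seed, {
    # dispersal-limited taxa: absent from a fixed fraction of samples
    n_zero <- ceiling(design$limited_zero_fraction * n)
    for (tx in design$limited_taxa) {
      z <- sample.int(n, n_zero)
      counts[tx, z] <- 0L
    }
    # correlated pairs active this season: shared latent sample ranking
    for (i in seq_len(nrow(design$pairs))) {
      active <- season %in% strsplit(design$pairs$seasons[i], ",")[[1]]
      if (!active) next
      a <- design$pairs$taxon_a[i]; b <- design$pairs$taxon_b[i]
      if (a %in% design$limited_taxa || b %in% design$limited_taxa)
        stop_endo("pair %s-%s overlaps a limited taxon in season %s",
                  a, b, season, class = "validation_error")
      latent <- sample.int(n) # shared sample-level factor (ranks)
      # wide spacing between consecutive counts so the monotone order (and
      # hence |rho| = 1) survives the mild thinning of a later rarefaction
      spacing <- 15L
      base_a <- max(1L, as.integer(round(mean(counts[a, ]))))
      base_b <- max(1L, as.integer(round(mean(counts[b, ]))))
      counts[a, ] <- base_a + spacing * latent
      counts[b, ] <- if (design$pairs$sign[i] == "positive")
        base_b + spacing * latent else base_b + spacing * ((n + 1L) - latent)
    }
    # host-selected taxa: present everywhere, at a floor of a few reads so
    # the planted presence is not erased by a later rarefaction step
    for (tx in design$selected_taxa) {
      low <- counts[tx, ] < 5L
      counts[tx, low] <- 5L
    }
    # exact renormalisation to depth
    for (j in seq_len(n)) {
      delta <- design$depth - sum(counts[, j])
      counts <- adjust_depth(counts, j, delta, protect = pl)
    }
  })
  abundance_table(counts, table$metadata)
}

#' Generate a full synthetic multi-season study
#'
#' Builds the site x tissue x season grid of abundance tables (neutral
#' backbone plus planted signals) together with a ground-truth manifest for
#' recovery scoring. Regenerating with the same design (and seed) is
#' bit-identical.
#'
#' @param design a `synthetic_design`.
#' @return an object of class `synthetic_study`: `tables` (named list,
#'   keys `site.tissue.season`), `table` (all samples merged into one
#'   `abundance_table` with design metadata), `manifest` (selected taxa,
#'   limited taxa, pair table) and `design`.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  pool <- make_pool(design)
  with_seed(derive_seed(design$seed, "study"), {
    pools <- seasonal_pools(design, pool)
    groups <- expand.grid(site = design$sites, tissue = design$tissues,
                          stringsAsFactors = FALSE)
    gmult <- lapply(seq_len(nrow(groups)), function(i)
      rlnorm(length(pool), 0, design$group_effect))
    tables <- list()
    for (season in design$seasons) {
      for (i in seq_len(nrow(groups))) {
        site <- groups$site[i]; tissue <- groups$tissue[i]
        p <- pools[[season]] * gmult[[i]]
        # keep pair taxa at their designed seasonal abundance
        pr <- c(design$pairs$taxon_a, design$pairs$taxon_b)
        p[pr] <- pools[[season]][pr]
        p <- p / sum(p)
        ids <- sprintf("%s_%s_%s_r%d", site, tissue, season,
                       seq_len(design$replicates))
        tab <- simulate_neutral_group(p, design$Nm, design$replicates,
                                      design$depth, sample_ids = ids)
        tab <- plant_signals(tab, design, season)
        tab$metadata$site <- site
        tab$metadata$tissue <- tissue
        tab$metadata$season <- season
        tab$metadata$replicate <- seq_len(design$replicates)
        tables[[paste(site, tissue, season, sep = ".")]] <- tab
      }
    }
    merged_counts <- do.call(cbind, lapply(tables, `[[`, "counts"))
    merged_meta <- do.call(rbind, lapply(tables, `[[`, "metadata"))
    manifest <- list(
      selected_taxa = design$selected_taxa,
      limited_taxa = design$limited_taxa,
      pairs = within(design$pairs, season_count <- lengths(
        strsplit(seasons, ",", fixed = TRUE))))
    structure(list(tables = tables,
                   table = abundance_table(merged_counts, merged_meta),
                   manifest = manifest, design = design),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d tables (%d samples total), depth %d\n",
              length(x$tables), ncol(x$table$counts), x$design$depth))
  print(x$design)
  invisible(x)
}
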