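# configuration-driven orchestration: load -> filter -> rarefy ->
# (diversity | beta tests | NCM + persistence | Raup-Crick | networks)

default_config <- function() {
  list(
    filter = list(min_total_count = 3, min_rel_abund = 0.001),
    rarefaction = list(depth = "min"),
    grouping = list(group_cols = c("site", "tissue"),
                    season_col = "season",
                    test_factors = c("site", "season")),
    params = list(n_perm = 999, n_boot = 1000, n_reps = 999,
                  rho_threshold = 0.8, p_threshold = 0.01,
                  min_seasons = 2, rci_threshold = 0.95,
                  hill_q = c(0, 1, 2), hill_n_boot = 100),
    seed = NULL # must be set explicitly: every run is reproducible
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

read_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_endo("YAML configs require the 'yaml' package",
                  class = "validation_error")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  merge_config(default_config(), config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_endo("pipeline stage '%s' failed: %s", name, conditionMessage(e),
              class = "pipeline_error")
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full seasonal-persistence analysis pipeline
#'
#' Executes, in dependency order: input loading (or synthetic-study
#' generation), low-abundance filtering, rarefaction, Hill-number
#' diversity, Bray-Curtis ordination and permutation tests, per-season
#' neutral-model fits with cross-season deviation persistence, Raup-Crick
#' stochasticity, and per-season co-occurrence networks combined into
#' season-persistence networks with their property records. Every
#' stochastic stage derives its own seed from the global seed and the
#' stage name, so re-running an identical configuration is bit-identical.
#'
#' @param config a configuration list, or the path of a JSON/YAML file.
#'   Recognised entries (all optional except an input):
#'   `input` (either `counts`/`metadata` file paths plus `format`, or
#'   `design`, a list of [synthetic_design()] arguments),
#'   `filter` (`min_total_count`, `min_rel_abund`),
#'   `rarefaction` (`depth`: `"min"` or a number),
#'   `grouping` (`group_cols`, `season_col`, `test_factors`),
#'   `params` (`n_perm`, `n_boot`, `n_reps`, `rho_threshold`,
#'   `p_threshold`, `min_seasons`, `rci_threshold`, `hill_q`,
#'   `hill_n_boot`), `seed`, `outdir`.
#' @param outdir output directory (overrides `config$outdir`); created if
#'   missing. When `NULL`, nothing is written and only the result list is
#'   returned.
#' @return invisibly, a list with the summary (also written as
#'   `summary.json`), per-stage results and output paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- read_config(config)
  outdir <- outdir %||% cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (is.null(cfg$seed))
    stop_endo("config must set a seed", class = "validation_error")
  seed <- cfg$seed
  paths <- list()
  emit <- function(df, name) {
    if (!is.null(outdir))
      paths[[name]] <<- write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
  }

  # ---- load / generate -------------------------------------------------
  study <- NULL
  tab <- stage("load", {
    if (!is.null(cfg$input$design)) {
      args <- cfg$input$design
      if (is.null(args$seed)) args$seed <- derive_seed(seed, "design")
      study <- do.call(synthetic_design, args)
      study <- generate_study(study)
      study$table
    } else if (!is.null(cfg$input$counts)) {
      read_abundance(cfg$input$counts,
                     format = cfg$input$format %||% "auto",
                     metadata = cfg$input$metadata)
    } else stop_endo("config$input must give `counts` or `design`",
                     class = "validation_error")
  })

  g <- cfg$grouping
  needed <- unique(c(g$group_cols, g$season_col, g$test_factors))
  absent <- setdiff(needed, names(tab$metadata))
  if (length(absent))
    stop_endo("metadata column(s) not found: %s",
              paste(absent, collapse = ", "), class = "validation_error")

  # ---- preprocess ------------------------------------------------------
  tab <- stage("filter", filter_taxa(tab, cfg$filter$min_total_count,
                                     cfg$filter$min_rel_abund))
  tab <- stage("rarefy", rarefy_table(tab, cfg$rarefaction$depth,
                                      seed = derive_seed(seed, "rarefy")))
  depth <- unique(colSums(tab$counts))
  meta <- tab$metadata
  group_of <- interaction(meta[g$group_cols], drop = TRUE, sep = ".")
  seasons <- unique(as.character(meta[[g$season_col]]))

  # ---- diversity -------------------------------------------------------
  diversity <- stage("diversity", {
    rows <- list()
    for (grp in levels(group_of)) {
      idx <- group_of == grp
      inc <- tab$counts[, idx, drop = FALSE]
      n_units <- sum(idx)
      sizes <- sort(unique(c(round(seq(1, 2 * n_units, length.out = 12)),
                             n_units)))
      for (q in cfg$params$hill_q) {
        cur <- hill_curve(inc, q = q, sizes = sizes,
                          n_boot = cfg$params$hill_n_boot,
                          seed = derive_seed(seed, paste0("hill.", grp, q)))
        cur$group <- grp
        rows[[paste(grp, q)]] <- cur
      }
    }
    do.call(rbind, rows)
  })
  emit(diversity, "diversity_curves")

  # ---- beta diversity --------------------------------------------------
  beta <- stage("beta", {
    d <- bray_curtis(tab)
    ord <- nmds(d, k = 2, seed = derive_seed(seed, "nmds"))
    tests <- list()
    for (tis in unique(meta$tissue %||% "all")) {
      idx <- if ("tissue" %in% names(meta)) meta$tissue == tis else
        rep(TRUE, nrow(meta))
      dsub <- as.dist(as.matrix(d)[idx, idx])
      for (f in g$test_factors) {
        if (f == "tissue") next
        grp_lab <- meta[[f]][idx]
        if (length(unique(grp_lab)) < 2) next
        key <- paste(tis, f, sep = ".")
        tests[[paste0("permanova.", key)]] <-
          permanova(dsub, grp_lab, n_perm = cfg$params$n_perm,
                    seed = derive_seed(seed, paste0("permanova.", key)))
        tests[[paste0("anosim.", key)]] <-
          anosim(dsub, grp_lab, n_perm = cfg$params$n_perm,
                 seed = derive_seed(seed, paste0("anosim.", key)))
      }
    }
    list(distance = d, nmds = ord, tests = tests)
  })
  test_tab <- do.call(rbind, lapply(names(beta$tests), function(nm) {
    t <- beta$tests[[nm]]
    data.frame(test = nm, statistic = t$statistic, r2 = t$r2, p = t$p,
               n_perm = t$n_perm, stringsAsFactors = FALSE)
  }))
  emit(test_tab, "beta_tests")
  if (!is.null(outdir)) {
    coords <- data.frame(sample_id = rownames(beta$nmds$points),
                         beta$nmds$points)
    emit(coords, "nmds_coordinates")
    dm <- as.matrix(beta$distance)
    emit(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
         "bray_curtis")
  }

  # ---- neutral model + persistence ------------------------------------
  ncm <- stage("ncm", {
    fits <- list(); persistence <- list()
    for (grp in levels(group_of)) {
      sfits <- list()
      for (season in seasons) {
        idx <- group_of == grp & meta[[g$season_col]] == season
        if (!any(idx)) next
        sub <- tab[, idx]
        sub <- sub[rowSums(sub$counts) > 0, ]
        sfits[[season]] <- fit_ncm(
          sub, depth = depth, n_boot = cfg$params$n_boot,
          seed = derive_seed(seed, paste0("ncm.", grp, ".", season)))
      }
      fits[[grp]] <- sfits
      pers <- persistence_across_seasons(sfits, min_count = length(sfits))
      if (nrow(pers)) pers$group <- grp
      persistence[[grp]] <- pers
    }
    list(fits = fits,
         persistence = do.call(rbind, persistence[lengths(persistence) > 0]))
  })
  fit_tab <- do.call(rbind, lapply(names(ncm$fits), function(grp)
    do.call(rbind, lapply(names(ncm$fits[[grp]]), function(season) {
      f <- ncm$fits[[grp]][[season]]
      data.frame(group = grp, season = season, Nm = f$Nm,
                 Nm_lower = f$Nm_ci[1], Nm_upper = f$Nm_ci[2], r2 = f$r2,
                 d = f$d, n_taxa = nrow(f$taxa), stringsAsFactors = FALSE)
    }))))
  emit(fit_tab, "ncm_fits")
  taxa_tab <- do.call(rbind, lapply(names(ncm$fits), function(grp)
    do.call(rbind, lapply(names(ncm$fits[[grp]]), function(season)
      cbind(data.frame(group = grp, season = season,
                       stringsAsFactors = FALSE),
            ncm$fits[[grp]][[season]]$taxa)))))
  emit(taxa_tab, "ncm_taxa")
  if (!is.null(ncm$persistence) && nrow(ncm$persistence))
    emit(ncm$persistence, "ncm_persistence")

  # ---- Raup-Crick ------------------------------------------------------
  rci <- stage("raupcrick", {
    out <- list()
    for (grp in levels(group_of)) {
      idx <- group_of == grp
      sub <- tab[, idx]
      sub <- sub[rowSums(sub$counts) > 0, ]
      rc <- raup_crick(sub, n_reps = cfg$params$n_reps,
                       seed = derive_seed(seed, paste0("rci.", grp)))
      frac <- stochastic_fraction(rc, threshold = cfg$params$rci_threshold,
                                  groups = sub$metadata[[g$season_col]])
      out[[grp]] <- list(rc = rc, stochastic_fraction = frac)
    }
    out
  })
  rci_tab <- do.call(rbind, lapply(names(rci), function(grp)
    data.frame(group = grp, stochastic_fraction = rci[[grp]]$stochastic_fraction,
               threshold = cfg$params$rci_threshold,
               n_reps = cfg$params$n_reps, stringsAsFactors = FALSE)))
  emit(rci_tab, "raup_crick")
  pair_tab <- do.call(rbind, lapply(names(rci), function(grp) {
    m <- rci[[grp]]$rc$rci
    ij <- which(upper.tri(m) & !is.na(m), arr.ind = TRUE)
    if (!nrow(ij)) return(NULL)
    data.frame(group = grp, sample_a = rownames(m)[ij[, 1]],
               sample_b = colnames(m)[ij[, 2]], rci = m[ij],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(pair_tab)) emit(pair_tab, "raup_crick_pairs")

  # ---- networks --------------------------------------------------------
  nets <- stage("network", {
    out <- list(); seasonal_all <- list()
    for (grp in levels(group_of)) {
      seasonal <- list()
      for (season in seasons) {
        idx <- group_of == grp & meta[[g$season_col]] == season
        if (sum(idx) < 4) next
        sub <- tab[, idx]
        seasonal[[season]] <- season_network(
          sub, rho_threshold = cfg$params$rho_threshold,
          p_threshold = cfg$params$p_threshold)
        seasonal_all[[paste(grp, season, sep = ".")]] <- seasonal[[season]]
      }
      combined <- combine_networks(seasonal,
                                   min_seasons = cfg$params$min_seasons)
      out[[grp]] <- list(seasonal = seasonal, combined = combined,
                         properties = network_properties(combined))
    }
    nonempty <- Filter(nrow, seasonal_all)
    ordination <- if (length(nonempty) >= 4)
      ordinate_networks(nonempty, seed = derive_seed(seed, "netnmds"))
    else NULL
    list(groups = out, ordination = ordination)
  })
  prop_tab <- do.call(rbind, lapply(names(nets$groups), function(grp)
    cbind(data.frame(group = grp, stringsAsFactors = FALSE),
          nets$groups[[grp]]$properties)))
  emit(prop_tab, "network_properties")
  edge_tab <- do.call(rbind, lapply(names(nets$groups), function(grp) {
    e <- nets$groups[[grp]]$combined$edges
    if (!nrow(e)) return(NULL)
    cbind(data.frame(group = grp, stringsAsFactors = FALSE), e)
  }))
  if (!is.null(edge_tab)) emit(edge_tab, "combined_network_edges")
  rare_tab <- do.call(rbind, lapply(names(nets$groups), function(grp) {
    cmb <- nets$groups[[grp]]$combined
    if (!nrow(cmb$edges)) return(NULL)
    idx <- group_of == grp
    cbind(data.frame(group = grp, stringsAsFactors = FALSE),
          flag_rare_nodes(cmb, tab$counts[, idx, drop = FALSE]))
  }))
  if (!is.null(rare_tab)) emit(rare_tab, "network_node_abundance")
  if (!is.null(outdir)) {
    for (grp in names(nets$groups)) {
      cmb <- nets$groups[[grp]]$combined
      if (nrow(cmb$edges))
        paths[[paste0("graphml.", grp)]] <-
          write_graphml(cmb, file.path(outdir,
                                       paste0("network_", grp, ".graphml")))
    }
  }

  # ---- summary ---------------------------------------------------------
  summary <- list(
    n_taxa = nrow(tab$counts), n_samples = ncol(tab$counts), depth = depth,
    seed = seed,
    beta_tests = if (!is.null(test_tab)) test_tab else NULL,
    nmds_stress = beta$nmds$stress,
    ncm = fit_tab,
    stochastic_fraction = rci_tab,
    networks = prop_tab,
    outputs = if (length(paths)) basename(unlist(paths)) else character())
  if (!is.null(outdir))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, table = tab, study = study,
                 diversity = diversity, beta = beta, ncm = ncm, rci = rci,
                 networks = nets, paths = paths))
}
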