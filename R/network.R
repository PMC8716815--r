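# per-season Spearman co-occurrence networks and the cross-season
# persistence network

# cache of exact Spearman null distributions (one per n)
.spearman_null_cache <- new.env(parent = emptyenv())

# all permutations of 1:n (n <= 9), one permutation per row
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

# sorted |rho| values over all n! rank permutations (untied ranks)
spearman_null_abs <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]]))
    return(.spearman_null_cache[[key]])
  perms <- all_permutations(n)
  d2 <- rowSums((perms - matrix(seq_len(n), nrow(perms), n, byrow = TRUE))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  out <- sort(abs(rho))
  .spearman_null_cache[[key]] <- out
  out
}

spearman_exact_p <- function(rho_obs, n) {
  null_abs <- spearman_null_abs(n)
  # two-sided: fraction of permutations at least as extreme
  m <- length(null_abs)
  (m - findInterval(abs(rho_obs) - 1e-9, null_abs)) / m
}

spearman_t_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1)
  p <- ifelse(r2 >= 1 - 1e-15, 0, {
    tval <- sqrt(r2) * sqrt((n - 2) / pmax(1 - r2, 1e-300))
    2 * pt(tval, n - 2, lower.tail = FALSE)
  })
  pmin(p, 1)
}

#' Spearman rank correlation test
#'
#' Computes Spearman's rho on average-ranked data with a two-sided p-value:
#' exact by full enumeration of the `n!` rank permutations when `n <= 9`
#' and neither vector has ties, and by the t approximation otherwise (the
#' behaviour of `cor.test`'s fallbacks).
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param method `"auto"` (exact when available), `"exact"` or `"t"`.
#' @return list with `rho`, `p`, `n` and `method` used.
#' @examples
#' spearman_test(1:5, c(2, 4, 6, 8, 10))  # rho = 1, exact p = 2/120
#' @export
spearman_test <- function(x, y, method = c("auto", "exact", "t")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L)
    stop_endo("need at least 4 paired observations", class = "validation_error")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_endo("rho undefined for a constant vector", class = "validation_error")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  exact_ok <- n <= 9L && !ties
  if (method == "exact" && !exact_ok)
    stop_endo("exact p requires n <= 9 and untied data",
              class = "validation_error")
  use_exact <- method == "exact" || (method == "auto" && exact_ok)
  p <- if (use_exact) spearman_exact_p(rho, n) else spearman_t_p(rho, n)
  list(rho = rho, p = p, n = n, method = if (use_exact) "exact" else "t")
}

#' Co-occurrence network of one sample slice
#'
#' Tests all unordered taxon pairs of an abundance-table slice (typically
#' one site x tissue x season, >= 4 samples) for Spearman co-occurrence and
#' keeps pairs with `|rho| > rho_threshold` and `p < p_threshold`. Taxa
#' with zero variance across the slice are skipped. The default p-value is
#' the t approximation: with few replicates the exact permutation p can
#' never reach conventional thresholds (at n = 5 its two-sided minimum is
#' 2/120), so the t approximation is what makes the gate operative --
#' matching how `cor.test` behaves on the tied count data such slices
#' produce.
#'
#' @param x an `abundance_table` (or taxa-by-samples matrix) with >= 4
#'   samples.
#' @param rho_threshold keep pairs with `|rho|` strictly above this.
#' @param p_threshold keep pairs with `p` strictly below this.
#' @param method `"t"` (default) or `"exact"` (exact where possible, i.e.
#'   n <= 9 and both vectors untied; tied pairs fall back to `"t"`).
#' @return data.frame of edges: `taxon_a`, `taxon_b`, `rho`, `p`, `sign`.
#' @export
season_network <- function(x, rho_threshold = 0.8, p_threshold = 0.01,
                           method = c("t", "exact")) {
  method <- match.arg(method)
  counts <- if (inherits(x, "abundance_table")) x$counts else as.matrix(x)
  n <- ncol(counts)
  if (n < 4L)
    stop_endo("co-occurrence screening needs at least 4 samples (have %d)",
              n, class = "validation_error")
  keep <- apply(counts, 1, function(v) length(unique(v)) > 1L)
  counts <- counts[keep, , drop = FALSE]
  empty <- data.frame(taxon_a = character(), taxon_b = character(),
                      rho = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (nrow(counts) < 2L) return(empty)
  ranks <- t(apply(counts, 1, rank))
  rho <- cor(t(ranks))
  tied <- apply(ranks, 1, anyDuplicated) > 0L
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  rho_v <- rho[ut]
  p_v <- spearman_t_p(rho_v, n)
  if (method == "exact" && n <= 9L) {
    exact_pair <- !tied[ut[, 1]] & !tied[ut[, 2]]
    if (any(exact_pair))
      p_v[exact_pair] <- spearman_exact_p(rho_v[exact_pair], n)
  }
  sel <- abs(rho_v) > rho_threshold & p_v < p_threshold
  if (!any(sel)) return(empty)
  ids <- rownames(counts)
  a <- ids[ut[sel, 1]]; b <- ids[ut[sel, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(taxon_a = a, taxon_b = b, rho = rho_v[sel], p = p_v[sel],
                    sign = ifelse(rho_v[sel] > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out[order(out$taxon_a, out$taxon_b), ]
}

edge_key <- function(edges, match_sign = TRUE) {
  if (!nrow(edges)) return(character())
  a <- pmin(edges$taxon_a, edges$taxon_b)
  b <- pmax(edges$taxon_a, edges$taxon_b)
  if (match_sign) paste(a, b, edges$sign, sep = "\r")
  else paste(a, b, sep = "\r")
}

#' Combine seasonal networks into a persistence network
#'
#' An edge identity is the unordered taxon pair (plus the correlation sign
#' when `match_sign = TRUE`, the default: a positive and a negative
#' association are different relationships). Edges observed in at least
#' `min_seasons` seasonal networks are kept; `kept_ratio` records (edges
#' kept, distinct edges seen in >= 1 season).
#'
#' @param seasonal named list of 2-4 seasonal edge data.frames (as returned
#'   by [season_network()]); names are the season labels.
#' @param min_seasons minimum number of seasons an edge must appear in.
#' @param match_sign include the correlation sign in the edge identity.
#' @return an object of class `combined_network`: `edges` (taxon_a,
#'   taxon_b, sign, seasons, season_count, mean_rho), `nodes` (endpoints of
#'   kept edges), `kept_ratio`, `min_seasons`, `match_sign`.
#' @export
combine_networks <- function(seasonal, min_seasons = 2, match_sign = TRUE) {
  stopifnot(is.list(seasonal), length(seasonal) >= 2L, length(seasonal) <= 4L)
  if (is.null(names(seasonal)) || anyDuplicated(names(seasonal)) ||
      any(names(seasonal) == ""))
    stop_endo("seasonal edge lists must be uniquely named",
              class = "validation_error")
  rows <- list()
  for (season in names(seasonal)) {
    e <- seasonal[[season]]
    if (!nrow(e)) next
    rows[[season]] <- data.frame(key = edge_key(e, match_sign),
                                 season = season, rho = e$rho,
                                 stringsAsFactors = FALSE)
  }
  all <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), season = character(), rho = numeric())
  total <- length(unique(all$key))
  agg <- lapply(split(all, all$key), function(g) {
    parts <- strsplit(g$key[1], "\r", fixed = TRUE)[[1]]
    data.frame(taxon_a = parts[1], taxon_b = parts[2],
               sign = if (match_sign) parts[3] else
                 ifelse(mean(g$rho) > 0, "positive", "negative"),
               seasons = paste(sort(unique(g$season)), collapse = ","),
               season_count = length(unique(g$season)),
               mean_rho = mean(g$rho), stringsAsFactors = FALSE)
  })
  edges <- if (length(agg)) do.call(rbind, agg) else
    data.frame(taxon_a = character(), taxon_b = character(),
               sign = character(), seasons = character(),
               season_count = integer(), mean_rho = numeric(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges <- edges[edges$season_count >= min_seasons, , drop = FALSE]
  edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$taxon_a, edges$taxon_b))),
                 kept_ratio = c(kept = nrow(edges), candidates = total),
                 min_seasons = min_seasons, match_sign = match_sign),
            class = "combined_network")
}

#' @export
print.combined_network <- function(x, ...) {
  cat(sprintf(
    "combined network (>= %d seasons): %d nodes, %d edges (%d/%d kept)\n",
    x$min_seasons, length(x$nodes), nrow(x$edges),
    x$kept_ratio["kept"], x$kept_ratio["candidates"]))
  invisible(x)
}

#' Convert edges to an igraph graph
#' @param x a `combined_network` or an edge data.frame.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(x) {
  edges <- if (inherits(x, "combined_network")) x$edges else x
  if (!nrow(edges)) return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(edges[, c("taxon_a", "taxon_b")],
                                directed = FALSE)
}

#' Flag rare taxa among the nodes of a network
#'
#' Connected taxa in season-persistence networks tend to be rare; this
#' helper annotates each node with its group-level relative abundance
#' (taxon total over grand total of the table the network was built from)
#' and flags nodes under the threshold.
#'
#' @param net a `combined_network` or edge data.frame.
#' @param table the `abundance_table` (or count matrix) of the group.
#' @param threshold relative-abundance threshold for the `rare` flag.
#' @return data.frame with `node`, `rel_abundance`, `rare`.
#' @export
flag_rare_nodes <- function(net, table, threshold = 0.005) {
  edges <- if (inherits(net, "combined_network")) net$edges else net
  nodes <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  counts <- if (inherits(table, "abundance_table")) table$counts
            else as.matrix(table)
  rel <- rowSums(counts)[nodes] / sum(as.numeric(counts))
  rel[is.na(rel)] <- 0
  data.frame(node = nodes, rel_abundance = unname(rel),
             rare = unname(rel) < threshold, stringsAsFactors = FALSE)
}

#' Write a network as GraphML
#'
#' @param net a `combined_network`, edge data.frame or igraph graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Graph-level properties of a co-occurrence network
#'
#' Node and edge counts, edge density with the ordered-pair denominator
#' `E / (V * (V - 1))`, global transitivity, diameter (longest finite
#' shortest path), and Freeman centralisation of closeness (computed over
#' reachable pairs), eigenvector centrality and betweenness.
#'
#' @param net a `combined_network`, edge data.frame or igraph graph.
#' @return one-row data.frame: `node_no`, `edge_no`, `edge_density`,
#'   `transitivity`, `diameter`, `centralized_closeness`,
#'   `centralized_eigenvector`, `centralized_betweenness`.
#' @export
network_properties <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  v <- igraph::vcount(g); e <- igraph::ecount(g)
  if (v == 0L || e == 0L) {
    warning("empty graph: returning an all-zero property record")
    return(data.frame(node_no = v, edge_no = e, edge_density = 0,
                      transitivity = 0, diameter = 0,
                      centralized_closeness = 0,
                      centralized_eigenvector = 0,
                      centralized_betweenness = 0))
  }
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) tr <- 0
  suppressWarnings({
    cc <- igraph::centr_clo(g, normalized = TRUE)$centralization
    ce <- eigen_centralization(g)
    cb <- igraph::centr_betw(g, normalized = TRUE)$centralization
  })
  data.frame(node_no = v, edge_no = e,
             edge_density = e / (v * (v - 1)),
             transitivity = tr,
             diameter = igraph::diameter(g),
             centralized_closeness = if (is.nan(cc)) 0 else cc,
             centralized_eigenvector = ce,
             centralized_betweenness = cb)
}

# Freeman centralization of eigenvector centrality, computed with a dense
# symmetric eigendecomposition (deterministic, unlike iterative solvers
# with random starts) and igraph's theoretical maximum for normalisation
eigen_centralization <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  v <- abs(eigen(A, symmetric = TRUE)$vectors[, 1])
  if (max(v) <= 0) return(0)
  v <- v / max(v)
  sum(max(v) - v) / igraph::centr_eigen_tmax(g)
}

#' Structural dissimilarity between two networks
#'
#' Jaccard distance between edge-identity sets:
#' `1 - |E_a intersect E_b| / |E_a union E_b|`. Zero iff the edge sets are
#' identical; 1 for disjoint sets.
#'
#' @param a,b `combined_network` objects or edge data.frames; at least one
#'   must be non-empty.
#' @param match_sign include the correlation sign in edge identity.
#' @return a number in `[0, 1]`.
#' @export
network_dissimilarity <- function(a, b, match_sign = TRUE) {
  ka <- edge_key(if (inherits(a, "combined_network")) a$edges else a,
                 match_sign)
  kb <- edge_key(if (inherits(b, "combined_network")) b$edges else b,
                 match_sign)
  u <- length(union(ka, kb))
  if (u == 0L)
    stop_endo("both networks are empty; dissimilarity undefined",
              class = "validation_error")
  1 - length(intersect(ka, kb)) / u
}

#' NMDS ordination of a set of networks
#'
#' Computes all pairwise structural dissimilarities (Jaccard on edge sets)
#' among the given networks and ordinates the resulting distance matrix
#' with [nmds()].
#'
#' @param nets named list of >= 4 networks (`combined_network` or edge
#'   data.frames).
#' @param k,n_starts,seed passed to [nmds()].
#' @param match_sign passed to [network_dissimilarity()].
#' @return an `nmds_fit` (the dissimilarity matrix is attached as
#'   attribute `"dissimilarity"`).
#' @export
ordinate_networks <- function(nets, k = 2, n_starts = 20, seed = NULL,
                              match_sign = TRUE) {
  stopifnot(is.list(nets), length(nets) >= 4L)
  m <- length(nets)
  d <- matrix(0, m, m, dimnames = list(names(nets), names(nets)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    d[i, j] <- d[j, i] <- network_dissimilarity(nets[[i]], nets[[j]],
                                                match_sign)
  fit <- nmds(as.dist(d), k = k, n_starts = n_starts, seed = seed)
  attr(fit, "dissimilarity") <- d
  fit
}
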