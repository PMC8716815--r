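# Spearman tests, seasonal networks, the combined persistence network and
# its graph properties

test_that("Spearman test matches enumeration and cor.test", {
  r <- spearman_test(1:5, c(3, 5, 8, 9, 20))
  expect_equal(r$rho, 1)
  expect_equal(r$p, 2 / 120) # both tails of the 120 rank permutations
  expect_identical(r$method, "exact")
  # antisymmetry
  set.seed(1)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_test(x, -y)$rho, -spearman_test(x, y)$rho)
  # agreement with cor.test's exact and t-approximation branches
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- spearman_test(x, y)
    ref <- cor.test(x, y, method = "spearman")
    expect_equal(ours$rho, unname(ref$estimate))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    ours_t <- spearman_test(x, y, method = "t")
    ref_t <- cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(ours_t$p, ref_t$p.value, tolerance = 1e-10)
  }
  expect_error(spearman_test(1:3, 3:1), "at least 4")
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("seasonal networks keep planted signals and respect preconditions", {
  set.seed(2)
  base <- matrix(rpois(40 * 5, 30), 40, 5,
                 dimnames = list(sprintf("t%02d", 1:40), paste0("s", 1:5)))
  base[1, ] <- c(10, 20, 30, 40, 50)   # proportional pair
  base[2, ] <- c(11, 22, 33, 44, 55)
  edges <- season_network(abundance_table(base))
  hit <- edges[edges$taxon_a == "t01" & edges$taxon_b == "t02", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rho, 1)
  expect_identical(hit$sign, "positive")
  expect_error(season_network(abundance_table(base[, 1:3])), "4 samples")
  # invariance to sample and taxon ordering
  perm_s <- c(4, 1, 5, 2, 3); perm_t <- sample(40)
  edges2 <- season_network(abundance_table(base[perm_t, perm_s]))
  key <- function(e) paste(e$taxon_a, e$taxon_b, e$sign)
  expect_setequal(key(edges2), key(edges))
})

test_that("chance perfect alignments occur at the enumeration null rate", {
  # at n = 5 the |rho| > 0.8 & p < 0.01 gate (t approximation) passes only
  # rho = +/-1, each with probability 1/120 for independent untied vectors
  set.seed(33)
  n_taxa <- 60
  m <- matrix(rnorm(n_taxa * 5), n_taxa, 5,
              dimnames = list(sprintf("t%02d", 1:n_taxa), paste0("s", 1:5)))
  edges <- season_network(m)
  n_pairs <- choose(n_taxa, 2)
  expected <- n_pairs * 2 / 120
  se <- sqrt(n_pairs * (2 / 120) * (1 - 2 / 120))
  expect_lt(abs(nrow(edges) - expected), 4 * se + 1)
  expect_true(all(abs(abs(edges$rho) - 1) < 1e-12))
})

test_that("combining networks applies the season-count and sign rules", {
  e <- function(a, b, rho) data.frame(taxon_a = a, taxon_b = b, rho = rho,
                                      p = 0, sign = ifelse(rho > 0,
                                                           "positive",
                                                           "negative"),
                                      stringsAsFactors = FALSE)
  seasonal <- list(
    spring = rbind(e("a", "b", 1), e("c", "d", 1)),
    summer = rbind(e("a", "b", 1), e("c", "d", -1)),
    autumn = e("e", "f", 1),
    winter = e("x", "y", -1))
  cn <- combine_networks(seasonal, min_seasons = 2)
  # a-b kept with count 2; c-d sign-split -> both identities dropped;
  # singletons dropped
  expect_equal(nrow(cn$edges), 1L)
  expect_equal(cn$edges$taxon_a, "a")
  expect_equal(cn$edges$season_count, 2L)
  expect_equal(unname(cn$kept_ratio), c(1L, 5L))
  expect_identical(cn$nodes, c("a", "b"))
  # ignoring the sign merges the c-d identities
  cn2 <- combine_networks(seasonal, min_seasons = 2, match_sign = FALSE)
  expect_setequal(cn2$edges$taxon_a, c("a", "c"))
  expect_error(combine_networks(setNames(seasonal, rep("s", 4))),
               "uniquely named")
  # reconstruction: every kept edge is present in >= min_seasons lists
  keys_by_season <- lapply(seasonal, function(x) paste(x$taxon_a, x$taxon_b,
                                                       x$sign))
  for (i in seq_len(nrow(cn$edges))) {
    k <- paste(cn$edges$taxon_a[i], cn$edges$taxon_b[i], cn$edges$sign[i])
    expect_gte(sum(vapply(keys_by_season, function(ks) k %in% ks,
                          logical(1))), 2L)
  }
})

test_that("graph properties use the ordered-pair density and igraph metrics", {
  e <- function(a, b) data.frame(taxon_a = a, taxon_b = b, rho = 1, p = 0,
                                 sign = "positive", stringsAsFactors = FALSE)
  triangle <- rbind(e("a", "b"), e("b", "c"), e("a", "c"))
  pr <- network_properties(triangle)
  expect_equal(pr$edge_density, 3 / 6)
  expect_equal(pr$transitivity, 1)
  expect_equal(pr$diameter, 1)
  path3 <- rbind(e("a", "b"), e("b", "c"))
  pr3 <- network_properties(path3)
  expect_equal(pr3$transitivity, 0)
  expect_equal(pr3$diameter, 2)
  expect_equal(pr3$edge_density, 2 / 6)
  # star graph: closeness/betweenness centralization at their maxima
  star <- rbind(e("h", "a"), e("h", "b"), e("h", "c"), e("h", "d"))
  prs <- network_properties(star)
  expect_equal(prs$centralized_betweenness, 1)
  expect_equal(prs$centralized_closeness, 1)
  expect_warning(pr0 <- network_properties(triangle[0, ]), "empty")
  expect_equal(pr0$node_no, 0L)
})

test_that("rare nodes are flagged and networks export as GraphML", {
  e <- data.frame(taxon_a = c("t01", "t02"), taxon_b = c("t02", "t03"),
                  rho = 1, p = 0, sign = "positive",
                  stringsAsFactors = FALSE)
  counts <- toy_counts(c(2, 500, 1, 1, 495, 1), 3, 2) # t02 dominant
  flags <- flag_rare_nodes(e, counts, threshold = 0.005)
  expect_identical(flags$node, c("t01", "t02", "t03"))
  expect_identical(flags$rare, c(TRUE, FALSE, TRUE))
  expect_equal(flags$rel_abundance[2], 995 / 1000)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(e, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 2)
})

test_that("structural dissimilarity is the Jaccard distance on edge sets", {
  e <- function(a, b) data.frame(taxon_a = a, taxon_b = b, rho = 1, p = 0,
                                 sign = "positive", stringsAsFactors = FALSE)
  n1 <- rbind(e("a", "b"), e("c", "d"))
  n2 <- rbind(e("c", "d"), e("e", "f"))
  expect_equal(network_dissimilarity(n1, n1), 0)
  expect_equal(network_dissimilarity(n1, rbind(e("x", "y"))), 1)
  expect_equal(network_dissimilarity(n1, n2), 1 - 1 / 3)
  expect_error(network_dissimilarity(n1[0, ], n2[0, ]), "empty")
})

test_that("network ordination separates structurally distinct clusters", {
  e <- function(a, b) data.frame(taxon_a = a, taxon_b = b, rho = 1, p = 0,
                                 sign = "positive", stringsAsFactors = FALSE)
  base1 <- rbind(e("a", "b"), e("b", "c"), e("c", "d"), e("d", "e"))
  base2 <- rbind(e("p", "q"), e("q", "r"), e("r", "s"), e("s", "t"))
  nets <- list(a1 = base1, a2 = rbind(base1[-1, ], e("a", "c")),
               b1 = base2, b2 = rbind(base2[-1, ], e("p", "r")))
  ord <- suppressWarnings(ordinate_networks(nets, seed = 4, n_starts = 5))
  expect_true(is.finite(ord$stress))
  pts <- ord$points
  within <- c(dist(pts[c("a1", "a2"), ]), dist(pts[c("b1", "b2"), ]))
  between <- as.vector(dist(pts))[c(2, 3, 4, 5)]
  expect_gt(min(between), max(within))
})
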