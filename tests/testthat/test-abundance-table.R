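# data model: construction, I/O, filtering, rarefaction, taxon statistics

test_that("tables round-trip through TSV/CSV and validate their invariants", {
  tab <- toy_table(c(5, 0, 3, 2, 1, 4), 3, 2,
                   meta = data.frame(sample_id = c("s01", "s02"),
                                     site = "control", tissue = "root",
                                     season = "spring", replicate = 1:2))
  expect_equal(dim(tab), c(3L, 2L))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  meta_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(tab, tsv, metadata_path = meta_tsv)
  back <- read_abundance(tsv, metadata = meta_tsv)
  expect_identical(back$counts, tab$counts)
  expect_equal(back$metadata$season, tab$metadata$season)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_abundance(tab, csv)
  expect_identical(read_abundance(csv)$counts, tab$counts)

  # malformed inputs
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\ts1\ts2", "a\t1\t2", "a\t3\t4"), bad)
  expect_error(read_abundance(bad), "duplicate")
  m <- toy_counts(1:4, 2, 2)
  m[1, 1] <- -1L
  expect_error(abundance_table(m), "egative")
  expect_error(abundance_table(toy_counts(1:4, 2, 2),
                               data.frame(sample_id = "s01")),
               "missing")
})

test_that("BIOM (JSON) tables load into the same model", {
  m <- toy_counts(c(5, 0, 3, 2, 1, 4), 3, 2)
  b <- biomformat::make_biom(m)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  back <- read_abundance(path, format = "biom")
  expect_equal(back$counts[rownames(m), colnames(m)], m)
})

test_that("low-abundance filtering follows total-count and share thresholds", {
  # taxon totals 1, 2, 500: default singleton/doubleton removal
  tab <- toy_table(c(1, 2, 500, 0, 0, 0), 3, 2)
  filt <- filter_taxa(tab, min_total_count = 3, min_rel_abund = 0)
  expect_identical(rownames(filt$counts), "t03")
  expect_identical(colnames(filt$counts), colnames(tab$counts))

  # share 5/10000 < 0.001 is removed
  m <- toy_counts(c(5, 9995), 2, 1)
  filt2 <- filter_taxa(abundance_table(m), 0, 0.001)
  expect_identical(rownames(filt2$counts), "t02")

  # zero thresholds: identity; same thresholds twice: idempotent
  tab3 <- random_table(seed = 4)
  expect_identical(filter_taxa(tab3, 0, 0)$counts, tab3$counts)
  once <- filter_taxa(tab3, 3, 0.01)
  expect_identical(filter_taxa(once, 3, 0.01)$counts, once$counts)

  expect_error(filter_taxa(toy_table(c(1, 1), 2, 1), 3, 0), "all taxa")
})

test_that("rarefaction is an even without-replacement subsample", {
  # a sample already at depth is unchanged
  tab <- toy_table(c(300, 200, 400, 100), 2, 2)
  r <- rarefy_table(tab, 500, seed = 1)
  expect_identical(r$counts, tab$counts)

  # single-taxon sample: (1000, 0) -> (500, 0)
  one <- toy_table(c(1000, 0), 2, 1)
  expect_equal(as.vector(rarefy_table(one, 500, seed = 1)$counts), c(500, 0))

  # column sums hit the depth exactly; absent taxa stay absent; reproducible
  tab2 <- random_table(n_taxa = 20, n_samples = 5, lambda = 80, seed = 2)
  tab2$counts[3, ] <- 0L
  r2 <- rarefy_table(tab2, 300, seed = 9)
  expect_true(all(colSums(r2$counts) == 300))
  expect_true(all(r2$counts[3, ] == 0))
  expect_identical(rarefy_table(tab2, 300, seed = 9)$counts, r2$counts)

  # shallow samples are dropped with a warning; error when none reach depth
  tab3 <- toy_table(c(600, 0, 100, 100), 2, 2)
  expect_warning(r3 <- rarefy_table(tab3, 400, seed = 1), "dropping")
  expect_identical(colnames(r3$counts), "s01")
  expect_error(suppressWarnings(rarefy_table(tab3, 5000)), "depth")
})

test_that("rarefied counts have the hypergeometric expectation", {
  # taxon with share 0.4: E[count in a 1000-read subsample] = 400
  tab <- toy_table(c(4000, 6000), 2, 1)
  draws <- vapply(seq_len(1000), function(s)
    rarefy_table(tab, 1000, seed = s)$counts[1, 1], numeric(1))
  v <- 1000 * 0.4 * 0.6 * (10000 - 1000) / (10000 - 1)
  se <- sqrt(v / length(draws))
  expect_lt(abs(mean(draws) - 400), 3 * se)
})

test_that("taxon statistics give mean relative abundance and occupancy", {
  expect_equal(taxon_stats(toy_table(c(50, 50, 50, 50), 2, 2))$p, c(t01 = 0.5, t02 = 0.5))
  st <- taxon_stats(toy_table(c(100, 0, 0, 100), 2, 2))
  expect_equal(unname(st$p), c(0.5, 0.5))
  expect_equal(unname(st$freq), c(0.5, 0.5))
  st2 <- taxon_stats(toy_table(c(90, 10, 50, 50), 2, 2))
  expect_equal(unname(st2$p), c(0.7, 0.3))
  expect_error(taxon_stats(toy_table(c(1, 0, 0, 0), 2, 2)), "zero total")

  # p sums to one on any valid table
  for (seed in 1:5) {
    tab <- random_table(seed = seed)
    expect_equal(sum(taxon_stats(tab)$p), 1, tolerance = 1e-9)
  }
})

test_that("metadata-driven subsetting keeps counts and metadata aligned", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:4),
                     site = c("control", "control", "radiation", "radiation"),
                     season = c("spring", "summer", "spring", "summer"))
  tab <- toy_table(1:12, 3, 4, meta)
  sub <- subset_samples(tab, site = "control", season = "summer")
  expect_identical(colnames(sub$counts), "s02")
  expect_identical(sub$metadata$sample_id, "s02")
  expect_error(subset_samples(tab, plot = "x"), "plot")
})
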