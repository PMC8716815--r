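# Sloan neutral community model: prediction, fitting, deviation persistence

test_that("predicted occupancy matches beta-density quadrature", {
  cases <- expand.grid(p = c(0.0005, 0.003, 0.02, 0.3),
                       Nm = c(20, 500, 5000), d = c(1e-4, 1e-3))
  for (i in seq_len(nrow(cases))) {
    got <- ncm_predicted_freq(cases$p[i], cases$Nm[i], cases$d[i])
    expect_equal(got, ncm_oracle(cases$p[i], cases$Nm[i], cases$d[i]),
                 tolerance = 1e-8)
  }
})

test_that("predicted occupancy behaves like the model's limits", {
  d <- 1e-3
  # huge Nm: beta concentrates at p -> step function around d
  expect_gt(ncm_predicted_freq(2e-3, 1e9, d), 0.999)
  expect_lt(ncm_predicted_freq(5e-4, 1e9, d), 0.001)
  # symmetric beta at its median
  expect_equal(ncm_predicted_freq(0.5, 10, 0.5), 0.5, tolerance = 1e-12)
  # strictly increasing in p; increasing in Nm above the detection limit
  p_grid <- seq(1e-4, 0.05, length.out = 40)
  f <- ncm_predicted_freq(p_grid, 100, d)
  expect_true(all(diff(f) > 0))
  nm_grid <- c(5, 50, 500, 5000)
  f_nm <- vapply(nm_grid, function(nm) ncm_predicted_freq(0.01, nm, d),
                 numeric(1))
  expect_true(all(diff(f_nm) > 0))
  expect_error(ncm_predicted_freq(c(0.5, 1), 10, 0.1), "inside")
})

test_that("noiseless on-curve data recover Nm almost exactly", {
  p <- exp(seq(log(2e-4), log(0.05), length.out = 120))
  stats <- structure(list(taxon_id = sprintf("t%03d", seq_along(p)), p = p,
                          freq = ncm_predicted_freq(p, 200, 1e-4),
                          n_samples = 30L), class = "taxon_stats")
  fit <- fit_ncm(stats, depth = 1e4, n_boot = 0)
  expect_lt(abs(fit$Nm - 200) / 200, 0.01)
  expect_gt(fit$r2, 0.999)
})

test_that("deviation labels partition taxa consistently with the bands", {
  st <- generate_study(synthetic_design(seed = 21))
  sub <- subset_samples(filter_taxa(st$table),
                        site = "control", tissue = "root", season = "summer")
  sub <- sub[rowSums(sub$counts) > 0, ]
  fit <- fit_ncm(sub, depth = 7500, n_boot = 40, seed = 2)
  tx <- fit$taxa
  expect_true(all(tx$ci_lower <= tx$freq_hat + 1e-12))
  expect_true(all(tx$freq_hat <= tx$ci_upper + 1e-12))
  expect_true(all(tx$label %in% c("above", "neutral", "below")))
  expect_identical(tx$label == "above", tx$freq > tx$ci_upper)
  expect_identical(tx$label == "below", tx$freq < tx$ci_lower)
  # bootstrap interval brackets the point estimate
  expect_true(fit$Nm_ci[1] <= fit$Nm && fit$Nm <= fit$Nm_ci[2])
  # model-object surface
  expect_named(coef(fit), "Nm")
  expect_equal(unname(predict(fit)), tx$freq_hat)
  expect_equal(unname(residuals(fit)), tx$freq - tx$freq_hat)
  expect_output(print(summary(fit)), "deviation labels")
})

test_that("taxa forced to full occupancy at low abundance are labeled above", {
  set.seed(10)
  p <- c(exp(seq(log(2e-4), log(0.05), length.out = 60)), 3e-4, 4e-4)
  freq <- c(ncm_predicted_freq(p[1:60], 100, 1e-4) +
              rnorm(60, 0, 0.02), 1, 1)
  freq <- pmin(pmax(freq, 0.01), 1)
  stats <- structure(list(taxon_id = sprintf("t%02d", seq_along(p)), p = p,
                          freq = freq, n_samples = 20L),
                     class = "taxon_stats")
  fit <- fit_ncm(stats, depth = 1e4, n_boot = 0)
  expect_identical(fit$taxa$label[61:62], c("above", "above"))
})

test_that("bootstrap Nm interval tightens with more taxa", {
  p_big <- exp(seq(log(2e-4), log(0.05), length.out = 240))
  set.seed(5)
  make_stats <- function(p) {
    freq <- pmin(pmax(ncm_predicted_freq(p, 150, 1e-4) +
                        rnorm(length(p), 0, 0.05), 0), 1)
    structure(list(taxon_id = seq_along(p), p = p, freq = freq,
                   n_samples = 30L), class = "taxon_stats")
  }
  fit_small <- fit_ncm(make_stats(p_big[seq(1, 240, by = 4)]), depth = 1e4,
                       n_boot = 80, seed = 1)
  fit_big <- fit_ncm(make_stats(p_big), depth = 1e4, n_boot = 80, seed = 1)
  expect_lt(diff(fit_big$Nm_ci), diff(fit_small$Nm_ci))
})

test_that("cross-season persistence bookkeeping is exact", {
  mk_fit <- function(labels) {
    structure(list(taxa = data.frame(taxon = names(labels), label = labels,
                                     stringsAsFactors = FALSE)),
              class = "ncm_fit")
  }
  fits <- list(
    spring = mk_fit(c(a = "above", b = "above", c = "below")),
    summer = mk_fit(c(a = "above", b = "above")),
    autumn = mk_fit(c(a = "above", b = "below")),
    winter = mk_fit(c(a = "above", b = "neutral")))
  rec <- persistence_across_seasons(fits, min_count = 4)
  a <- rec[rec$taxon == "a" & rec$direction == "above", ]
  expect_equal(a$count, 4L)
  expect_true(a$persistent)
  expect_equal(a$seasons, "autumn,spring,summer,winter")
  b_above <- rec[rec$taxon == "b" & rec$direction == "above", ]
  b_below <- rec[rec$taxon == "b" & rec$direction == "below", ]
  expect_equal(b_above$count, 2L)
  expect_equal(b_below$count, 1L)
  expect_false(b_above$persistent)
  expect_error(persistence_across_seasons(setNames(fits, rep("spring", 4))),
               "uniquely named")
})
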