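# fixtures and independent oracles shared across test files

# small labelled count matrix
toy_counts <- function(vals, n_taxa, n_samples) {
  matrix(as.integer(vals), n_taxa, n_samples,
         dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                         sprintf("s%02d", seq_len(n_samples))))
}

toy_table <- function(vals, n_taxa, n_samples, meta = NULL) {
  abundance_table(toy_counts(vals, n_taxa, n_samples), meta)
}

# random abundance table under a fixed seed
random_table <- function(n_taxa = 12, n_samples = 6, lambda = 20,
                         seed = 1) {
  set.seed(seed)
  toy_table(rpois(n_taxa * n_samples, lambda) , n_taxa, n_samples)
}

# direct Bray-Curtis formula, independent of the implementation path
bray_oracle <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# quadrature oracle for the Sloan occupancy prediction: integral of the
# beta density above the detection limit
ncm_oracle <- function(p, Nm, d) {
  integrate(function(z) dbeta(z, Nm * p, Nm * (1 - p)), d, 1,
            rel.tol = 1e-10)$value
}

# a synthetic design without planted signals (pure neutral backbone)
neutral_design <- function(n_taxa = 300, seed = 1, ...) {
  synthetic_design(n_taxa = n_taxa, n_selected = 0, n_limited = 0,
                   pairs = data.frame(sign = character(),
                                      seasons = character(),
                                      stringsAsFactors = FALSE),
                   seed = seed, ...)
}

# two well-separated clusters of compositional samples; use n_per >= 10 so
# that duplicate label permutations (which tie the observed statistic) are
# vanishingly rare and the minimal permutation p is achievable
cluster_table <- function(n_per = 10, seed = 1) {
  set.seed(seed)
  a <- sapply(seq_len(n_per), function(i) rmultinom(1, 500, c(8, 8, 1, 1)))
  b <- sapply(seq_len(n_per), function(i) rmultinom(1, 500, c(1, 1, 8, 8)))
  m <- cbind(a, b)
  dimnames(m) <- list(paste0("t", 1:4), paste0("s", seq_len(2 * n_per)))
  list(table = abundance_table(m),
       groups = rep(c("A", "B"), each = n_per))
}
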