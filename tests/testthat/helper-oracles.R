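# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-sided Fisher p by direct enumeration of all 2x2 tables with the
# observed margins, hypergeometric pmf from binomial coefficients.
fisher_oracle <- function(c_a, n_a, c_b, n_b) {
  m <- c_a + c_b
  if (m == 0) return(1)
  ks <- max(0, m - n_b):min(m, n_a)
  pr <- choose(n_a, ks) * choose(n_b, m - ks) / choose(n_a + n_b, m)
  min(1, sum(pr[pr <= pr[ks == c_a] * (1 + 1e-7)]))
}

# G statistic by numeric maximisation of the Poisson log-likelihoods of the
# two libraries (alternative: free rates; null: one shared rate).
g_oracle <- function(c_a, n_a, c_b, n_b) {
  ll <- function(lam, cc, n) stats::dpois(cc, n * lam, log = TRUE)
  max1 <- function(cc, n) {
    up <- max(1, cc * 10) / n
    stats::optimize(function(l) ll(l, cc, n), c(1e-14, up),
                    maximum = TRUE, tol = 1e-13)$objective
  }
  null <- stats::optimize(
    function(l) ll(l, c_a, n_a) + ll(l, c_b, n_b),
    c(1e-14, max(1, (c_a + c_b) * 10) / (n_a + n_b)),
    maximum = TRUE, tol = 1e-13)$objective
  2 * (max1(c_a, n_a) + max1(c_b, n_b) - null)
}

# Small default simulation for pipeline-level tests (kept light: depth 1e5,
# 300 genes).
small_dataset <- function(seed = 11, ...) {
  simulate_experiment(sim_config(n_genes = 300, library_size = 1e5,
                                 n_per_class = 3, orf_min_aa = 30,
                                 seed = seed, ...))
}
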