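# shared fixtures and independent oracles for the test suite

rand_counts <- function(q, m, seed = 1L, lambda = 5) {
  withr::with_seed(seed, matrix(stats::rpois(q * m, lambda), q, m))
}

make_target <- function(family, lambda) {
  structure(list(family = family, lambda = lambda, rmse = 0,
                 fit_domain = c(0, 1)),
            class = "fitted_distribution")
}

# closed-form quantile functions, written out independently of the package
# internals, used as the brute-force equalization oracle
oracle_quantile <- function(family, p, lambda) {
  switch(family,
         exponential = -log(1 - p) / lambda,
         rayleigh = lambda * sqrt(-log(1 - p)),
         gaussian = lambda * stats::qnorm((p + 1) / 2) / sqrt(2))
}

# brute-force lut: discretized inverse-CDF of the clipped level CDF
oracle_lut <- function(family, lambda, cdf, L, n_elements) {
  eps <- 1 / (2 * n_elements)
  f <- pmin(pmax(cdf, 0), 1 - eps)
  z <- oracle_quantile(family, f, lambda)
  as.integer(pmin(floor(z / z[length(z)] * (L - 1) + 1e-9), L - 1))
}

# two-sample Kolmogorov-Smirnov statistic on integer-valued samples
ks_stat <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  fa <- cumsum(tabulate(match(a, lev), length(lev))) / length(a)
  fb <- cumsum(tabulate(match(b, lev), length(lev))) / length(b)
  max(abs(fa - fb))
}

# small dropout benchmark used by several pipeline tests
small_benchmark <- function(seed = 7L, efficiency = 1) {
  simulate_benchmark(group_sim_params(n_groups = 3L, n_cells_per_group = 60L,
                                      n_genes = 120L),
                     efficiency = efficiency, seed = seed)
}
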