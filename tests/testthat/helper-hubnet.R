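# Shared helpers: cached censuses (reused across acceptance blocks) and a
# convergence-probability shortcut for function-valued ensemble specs.

census_cache <- new.env(parent = emptyenv())

cached_census <- function(sigma_h, n = 16, n_realizations = 1e4,
                          seed = 20260900 + round(10 * sigma_h)) {
  key <- sprintf("s%g_n%d_r%d", sigma_h, n, n_realizations)
  if (is.null(census_cache[[key]]))
    census_cache[[key]] <- fixed_point_census(n, n_realizations,
                                              sigma_h = sigma_h, seed = seed)
  census_cache[[key]]
}

prob_at <- function(census, m) mean(census$M == m)

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

# two-sample binomial comparison: both values are finite-sample estimates
combined_se <- function(p1, n1, p2, n2 = n1) {
  sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}

# brute-force fixed-point oracle, independent of the Gray-code path
enumerate_fixed_points_oracle <- function(W, drive = NULL) {
  n <- ncol(W)
  if (is.null(drive)) drive <- numeric(n)
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  hits <- apply(states, 1, function(s) {
    x <- as.vector(W %*% s) + drive
    all(sign(x) == s)
  })
  sum(hits)
}
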