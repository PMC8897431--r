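# Brute-force statistical oracles, independent of the implementation
# paths they check.

# Mann-Whitney U by pair counting (ties count one half).
brute_mann_whitney_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Two-sample KS statistic as the sup distance between empirical CDFs,
# evaluated over the pooled support.
brute_ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t),
                 numeric(1))))
}

# 2x2 chi-square from the four cells directly.
brute_chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Small-config factory used across generator tests.
toy_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_samples = 20L, n_sites = 100L,
               n_mei_loci = 60L, n_nrs_contigs = 6L,
               chromosome_lengths = c(chr1 = 150000, chr2 = 100000))
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
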