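# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles (brute force, dense numerical
# integration, textbook formulas) and never call the implementation paths
# they check.

# Exhaustive shortest-window HDI over sorted draws.
brute_force_hdi <- function(draws, mass = 0.95) {
  s <- sort(draws)
  N <- length(s)
  m <- ceiling(mass * N)
  best <- c(-Inf, Inf)
  for (i in seq_len(N - m + 1L)) {
    lo <- s[i]; hi <- s[i + m - 1L]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# Dense 2-D grid posterior of the lognormal model with flat (mu, sigma)
# priors: returns weighted values of the posterior mean statistic, plus
# median and 95% HDI computed from the weighted discrete distribution.
grid_posterior_mean <- function(sample, prior = wqbench::prior_spec(),
                                n_mu = 600L, n_sigma = 600L) {
  x <- log(sample)
  n <- length(x)
  m <- mean(x)
  s_hat <- sqrt(mean((x - m)^2))
  mu_grid <- seq(max(prior$mu[1], m - 8 * s_hat / sqrt(n)),
                 min(prior$mu[2], m + 8 * s_hat / sqrt(n)),
                 length.out = n_mu)
  sg_grid <- seq(max(prior$sigma[1], s_hat / 4),
                 min(prior$sigma[2], s_hat * 4), length.out = n_sigma)
  lp <- matrix(NA_real_, n_mu, n_sigma)
  for (j in seq_len(n_sigma)) {
    sg <- sg_grid[j]
    lp[, j] <- -n * log(sg) - colSums((outer(x, mu_grid, "-"))^2) / (2 * sg^2)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  stat <- outer(mu_grid, sg_grid, function(mu, sg) exp(mu + sg^2 / 2))
  o <- order(as.vector(stat))
  vals <- as.vector(stat)[o]
  probs <- as.vector(w)[o]
  cum <- cumsum(probs)
  median_stat <- vals[which(cum >= 0.5)[1]]
  # weighted shortest-interval HDI over the sorted discrete distribution
  lo_idx <- 1L
  best <- c(vals[1], vals[length(vals)])
  hi_idx <- 1L
  for (lo_idx in seq_along(vals)) {
    c_lo <- if (lo_idx == 1L) 0 else cum[lo_idx - 1L]
    hi_idx <- which(cum - c_lo >= 0.95)[1]
    if (is.na(hi_idx)) break
    if (vals[hi_idx] - vals[lo_idx] < best[2] - best[1])
      best <- c(vals[lo_idx], vals[hi_idx])
  }
  list(median = median_stat, hdi = best)
}

# Textbook Gelman-Rubin potential scale reduction, written independently.
textbook_gelman_rubin <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  chain_means <- sapply(chains, mean)
  grand <- mean(chain_means)
  B <- n / (m - 1) * sum((chain_means - grand)^2)
  W <- mean(sapply(chains, function(ch) sum((ch - mean(ch))^2) / (n - 1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Convenience: a small seeded lognormal sample for fixture-style tests.
fixture_sample <- function(n = 36L, seed = 101L, meanlog = -3.5, sdlog = 0.8) {
  withr::with_seed(seed, rlnorm(n, meanlog, sdlog))
}
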