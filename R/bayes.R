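#' Uniform prior box for the lognormal model
#'
#' Independent uniform priors on the log-scale location `mu` and spread
#' `sigma` of the lognormal model, each restricted to a finite interval.
#' The defaults, mu in \[-20, 5\] (log mg P/L) and sigma in \[1e-4, 10\],
#' are vague for any realistic nutrient concentration; a bound-saturation
#' warning in [lognormal_posterior()] guards against data pushing
#' appreciable posterior mass onto the box edges. The flat prior is placed
#' on sigma itself (not on sigma^2 or log sigma).
#'
#' @param mu_bounds Length-2 numeric, bounds for mu (log concentration).
#' @param sigma_bounds Length-2 numeric, bounds for sigma (> 0 lower bound
#'   allowed down to 0).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_bounds = c(-20, 5), sigma_bounds = c(1e-4, 10)) {
  stopifnot(length(mu_bounds) == 2L, length(sigma_bounds) == 2L,
            all(is.finite(mu_bounds)), all(is.finite(sigma_bounds)))
  if (mu_bounds[1] >= mu_bounds[2] || sigma_bounds[1] >= sigma_bounds[2])
    stop_arg("prior bounds must satisfy lower < upper")
  if (sigma_bounds[1] < 0) stop_arg("sigma lower bound must be >= 0")
  structure(list(mu = as.numeric(mu_bounds), sigma = as.numeric(sigma_bounds)),
            class = "prior_spec")
}

#' Paired posterior draws of the mean and 95th percentile
#'
#' Container returned by the inference methods. Draw m of `draws_mean` and
#' `draws_q95` derive from the same parameter draw (lognormal model) or the
#' same Dirichlet weight vector (Bayesian bootstrap), so joint events over
#' both statistics can be evaluated draw-wise.
#'
#' @param method `"lognormal"` or `"bayesian_bootstrap"`.
#' @param draws_mean,draws_q95 Equal-length positive numeric vectors.
#' @param mu,sigma Optional parameter draws (lognormal method).
#' @return An object of class `posterior_draws`.
#' @export
posterior_draws <- function(method, draws_mean, draws_q95,
                            mu = NULL, sigma = NULL) {
  method <- match.arg(method, c("lognormal", "bayesian_bootstrap"))
  if (length(draws_mean) != length(draws_q95))
    stop_arg("draws_mean and draws_q95 must have equal length")
  if (any(draws_mean <= 0) || any(draws_q95 <= 0))
    stop_arg("all draws must be positive")
  structure(list(method = method, draws_mean = as.numeric(draws_mean),
                 draws_q95 = as.numeric(draws_q95), paired = TRUE,
                 mu = mu, sigma = sigma),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s, N = %d paired draws\n", x$method,
              length(x$draws_mean)))
  cat(sprintf("  mean: median %.4g  q95: median %.4g mg P/L\n",
              stats::median(x$draws_mean), stats::median(x$draws_q95)))
  invisible(x)
}

#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  df <- data.frame(draw = seq_along(x$draws_mean), mean = x$draws_mean,
                   q95 = x$draws_q95)
  if (!is.null(x$mu)) { df$mu <- x$mu; df$sigma <- x$sigma }
  df
}

#' Write posterior draws to CSV
#'
#' Columns: draw index, mean, q95 and, for the lognormal model, the
#' parameter draws mu and sigma.
#'
#' @param posterior A [posterior_draws()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(posterior, path) {
  utils::write.csv(as.data.frame(posterior), path, row.names = FALSE)
  invisible(path)
}

# log of the sigma marginal (mu integrated over its box analytically):
#   p(sigma) propto sigma^-(n-1) exp(-S/(2 sigma^2)) *
#             [Phi((mu_hi - m) sqrt(n)/sigma) - Phi((mu_lo - m) sqrt(n)/sigma)]
# with m = mean(log y), S = sum((log y - m)^2).
.log_sigma_marginal <- function(sigma, n, m, S, prior) {
  rt_n <- sqrt(n)
  dphi <- stats::pnorm((prior$mu[2] - m) * rt_n / sigma) -
          stats::pnorm((prior$mu[1] - m) * rt_n / sigma)
  -(n - 1) * log(sigma) - S / (2 * sigma^2) + log(pmax(dphi, 1e-300))
}

# Adaptive grid over the sigma marginal: coarse log-spaced scan around the
# ML spread, then a fine linear grid over the region of appreciable mass.
.sigma_grid <- function(n, m, S, prior, n_fine = 2048L) {
  sig_hat <- sqrt(S / n)
  lo <- max(prior$sigma[1], sig_hat / 100)
  hi <- min(prior$sigma[2], sig_hat * 100)
  if (lo >= hi) { lo <- prior$sigma[1]; hi <- prior$sigma[2] }
  coarse <- exp(seq(log(lo), log(hi), length.out = 512L))
  lf <- .log_sigma_marginal(coarse, n, m, S, prior)
  keep <- which(lf > max(lf) - 40)
  i0 <- max(1L, min(keep) - 1L); i1 <- min(length(coarse), max(keep) + 1L)
  fine <- seq(coarse[i0], coarse[i1], length.out = n_fine)
  lf_fine <- .log_sigma_marginal(fine, n, m, S, prior)
  w <- exp(lf_fine - max(lf_fine))
  # trapezoid cell masses on the fine grid
  dx <- diff(fine)
  cell <- dx * (w[-length(w)] + w[-1]) / 2
  list(grid = fine, weights = w, cell_prob = cell / sum(cell))
}

# Inverse-CDF draws of sigma from the fine-grid marginal, with linear
# placement within each grid cell.
.sample_sigma_grid <- function(g, n_draws) {
  cum <- c(0, cumsum(g$cell_prob))
  u <- stats::runif(n_draws)
  j <- findInterval(u, cum, rightmost.closed = TRUE)
  j[j < 1L] <- 1L; j[j > length(g$cell_prob)] <- length(g$cell_prob)
  frac <- (u - cum[j]) / pmax(cum[j + 1L] - cum[j], 1e-300)
  g$grid[j] + frac * (g$grid[j + 1L] - g$grid[j])
}

# mu | sigma is Normal(m, sigma/sqrt(n)) truncated to the prior box;
# inverse-CDF sampling. Returns draws and the average truncated-away mass.
.sample_mu_given_sigma <- function(sigma, n, m, prior) {
  sd_mu <- sigma / sqrt(n)
  pa <- stats::pnorm(prior$mu[1], m, sd_mu)
  pb <- stats::pnorm(prior$mu[2], m, sd_mu)
  u <- stats::runif(length(sigma))
  mu <- stats::qnorm(pa + u * (pb - pa), m, sd_mu)
  list(mu = pmin(pmax(mu, prior$mu[1]), prior$mu[2]),
       trunc_mass = mean(pa + (1 - pb)))
}

.check_saturation <- function(mu, sigma, prior) {
  edge <- function(x, b) {
    r <- b[2] - b[1]
    mean(x < b[1] + 0.005 * r | x > b[2] - 0.005 * r)
  }
  sat <- max(edge(mu, prior$mu), edge(sigma, prior$sigma))
  if (sat > 0.01)
    warning(sprintf(paste0("posterior mass at prior bounds (%.1f%%): ",
                           "prior box may be too tight"), 100 * sat))
}

#' Posterior of the mean and 95th percentile under the lognormal model
#'
#' Fits the two-parameter lognormal distribution to a low-frequency sample
#' with independent uniform priors on (mu, sigma) restricted to the
#' [prior_spec()] box. The posterior density is proportional to
#' `sigma^-n exp(-sum((log y - mu)^2) / (2 sigma^2))` on the box. Parameter
#' draws are transformed to the derived statistics
#' `mean = exp(mu + sigma^2/2)` and `q95 = exp(mu + z95 * sigma)` with
#' `z95 = qnorm(0.95)`, yielding paired posterior draws of both statistics.
#'
#' Two samplers are available. `mode = "exact"` (default) draws sigma by
#' inverse-CDF from its analytically marginalized posterior evaluated on an
#' adaptive grid, then mu from its conditional (truncated) normal — i.i.d.
#' draws, no burn-in needed. `mode = "mcmc"` runs a random-walk Metropolis
#' sampler that keeps `n_draws` iterates after an equal number of burn-in
#' iterations, mirroring the MCMC protocol typical of applied practice and
#' providing chains for [gelman_rubin()].
#'
#' @param sample Positive numeric vector, n >= 2, with nonzero spread.
#' @param n_draws Number of posterior draws to return (default 1000).
#' @param prior A [prior_spec()].
#' @param seed Integer seed, or `NULL`.
#' @param mode `"exact"` or `"mcmc"`.
#' @return A [posterior_draws()] object with parameter draws attached.
#' @export
lognormal_posterior <- function(sample, n_draws = 1000L,
                                prior = prior_spec(), seed = NULL,
                                mode = c("exact", "mcmc")) {
  mode <- match.arg(mode)
  assert_positive_values(sample, "sample")
  n <- length(sample)
  if (n < 2L) stop_arg("need at least 2 observations")
  x <- log(sample)
  m <- mean(x)
  S <- sum((x - m)^2)
  if (S == 0) stop_arg("degenerate sample: zero spread on the log scale")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop_arg("n_draws must be >= 1")

  draws <- with_seed_or_current(seed, {
    if (mode == "exact") {
      g <- .sigma_grid(n, m, S, prior)
      sigma <- .sample_sigma_grid(g, n_draws)
      mu <- .sample_mu_given_sigma(sigma, n, m, prior)$mu
      list(mu = mu, sigma = sigma)
    } else {
      .lognormal_mcmc(n, m, S, prior, n_draws)
    }
  })
  .check_saturation(draws$mu, draws$sigma, prior)
  posterior_draws("lognormal",
                  draws_mean = exp(draws$mu + draws$sigma^2 / 2),
                  draws_q95 = exp(draws$mu + z95() * draws$sigma),
                  mu = draws$mu, sigma = draws$sigma)
}

# Random-walk Metropolis on (mu, sigma) with the flat box prior; proposals
# outside the box are rejected. Proposal scales follow the large-sample
# posterior spreads sigma_hat/sqrt(n) and sigma_hat/sqrt(2n).
.lognormal_mcmc <- function(n, m, S, prior, n_draws, burn_in = n_draws) {
  log_post <- function(mu, sigma) {
    if (mu < prior$mu[1] || mu > prior$mu[2] ||
        sigma < prior$sigma[1] || sigma > prior$sigma[2]) return(-Inf)
    -n * log(sigma) - (S + n * (mu - m)^2) / (2 * sigma^2)
  }
  sig_hat <- sqrt(S / n)
  step_mu <- 2.4 * sig_hat / sqrt(n)
  step_sig <- 2.4 * sig_hat / sqrt(2 * n)
  mu_cur <- min(max(m, prior$mu[1]), prior$mu[2])
  sig_cur <- min(max(sig_hat, prior$sigma[1]), prior$sigma[2])
  lp_cur <- log_post(mu_cur, sig_cur)
  total <- burn_in + n_draws
  mu_out <- numeric(n_draws); sig_out <- numeric(n_draws)
  for (it in seq_len(total)) {
    mu_prop <- mu_cur + stats::rnorm(1, 0, step_mu)
    sig_prop <- sig_cur + stats::rnorm(1, 0, step_sig)
    lp_prop <- log_post(mu_prop, sig_prop)
    if (log(stats::runif(1)) < lp_prop - lp_cur) {
      mu_cur <- mu_prop; sig_cur <- sig_prop; lp_cur <- lp_prop
    }
    if (it > burn_in) {
      mu_out[it - burn_in] <- mu_cur
      sig_out[it - burn_in] <- sig_cur
    }
  }
  list(mu = mu_out, sigma = sig_out)
}

# Weighted 95th percentile of the discrete distribution {(y_i, w_i)}:
# smallest order statistic whose cumulative weight reaches p
# (left-continuous threshold rule, no interpolation), or linear
# interpolation between adjacent order statistics when interpolate = TRUE.
weighted_quantile_discrete <- function(sorted_y, w_sorted, p = 0.95,
                                       interpolate = FALSE) {
  cw <- cumsum(w_sorted)
  k <- findInterval(p, cw, left.open = TRUE) + 1L
  k <- min(k, length(sorted_y))
  if (!interpolate) return(sorted_y[k])
  if (k == 1L) return(sorted_y[1L])
  c0 <- cw[k - 1L]
  frac <- (p - c0) / pmax(cw[k] - c0, 1e-300)
  sorted_y[k - 1L] + frac * (sorted_y[k] - sorted_y[k - 1L])
}

#' Bayesian bootstrap posterior of the mean and 95th percentile
#'
#' Rubin's Bayesian bootstrap: each posterior draw places a flat
#' Dirichlet(1, ..., 1) weight vector on the n observed values and
#' evaluates the statistics of the weighted discrete distribution. The
#' mean draw is the weighted average; the 95th-percentile draw is, by
#' default, the smallest order statistic whose cumulative weight reaches
#' 0.95, so its posterior is supported on the observed values only
#' (discrete and typically multimodal). Set `interpolate = TRUE` for a
#' linearly interpolated variant.
#'
#' @param sample Positive numeric vector, n >= 2.
#' @param n_draws Number of Dirichlet draws (default 1000).
#' @param seed Integer seed, or `NULL`.
#' @param interpolate Interpolate the weighted quantile between order
#'   statistics? Default `FALSE` (discrete rule).
#' @return A [posterior_draws()] object.
#' @export
bayesian_bootstrap <- function(sample, n_draws = 1000L, seed = NULL,
                               interpolate = FALSE) {
  assert_positive_values(sample, "sample")
  n <- length(sample)
  if (n < 2L) stop_arg("need at least 2 observations")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop_arg("n_draws must be >= 1")
  ord <- order(sample)
  y_sorted <- sample[ord]
  with_seed_or_current(seed, {
    # Dirichlet(1,...,1) rows via normalized exponentials
    e <- matrix(stats::rexp(n_draws * n), nrow = n_draws, ncol = n)
    w <- e / rowSums(e)
    w_sorted <- w[, ord, drop = FALSE]
    draws_mean <- as.vector(w %*% sample)
    draws_q95 <- vapply(seq_len(n_draws), function(i)
      weighted_quantile_discrete(y_sorted, w_sorted[i, ], 0.95, interpolate),
      numeric(1))
    posterior_draws("bayesian_bootstrap", draws_mean, draws_q95)
  })
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance ratio: with m chains of
#' length n, `R = sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B/n` the variance of the chain means. Values
#' near 1 indicate convergence; values well above ~1.1 indicate that the
#' chains have not mixed.
#'
#' @param chains List of >= 2 equal-length numeric vectors (length >= 10).
#' @return Scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop_arg("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop_arg("chains must have equal lengths")
  if (n < 10L) stop_arg("chains must have length >= 10")
  m <- length(chains)
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}
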