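#' Fit result container
#'
#' @param spec Fitted [mixture_spec()].
#' @param loglik Total log-likelihood of the data at the fitted parameters.
#' @param n_iter Iterations used (1 for closed-form fits; EM iterations for
#'   mixtures).
#' @param converged Logical convergence flag.
#' @param loglik_trace Optional per-iteration log-likelihood trace (EM).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(spec, loglik, n_iter = 1L, converged = TRUE,
                       loglik_trace = NULL) {
  if (!is.finite(loglik)) stop_arg("loglik must be finite")
  structure(list(spec = spec, loglik = loglik, n_iter = as.integer(n_iter),
                 converged = isTRUE(converged), loglik_trace = loglik_trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> loglik = %.4f, %d iteration(s), converged = %s\n",
              x$loglik, x$n_iter, x$converged))
  print(x$spec)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes family, weights, components, loglik and the convergence flag.
#'
#' @param fit A [fit_result()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(family = fit$spec$family,
                            weights = fit$spec$weights,
                            components = fit$spec$components,
                            loglik = fit$loglik,
                            n_iter = fit$n_iter,
                            converged = fit$converged),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Maximum-likelihood fit of a unimodal distribution
#'
#' Fits a single lognormal, gamma or Weibull distribution to strictly
#' positive concentration data by maximum likelihood. The lognormal fit is
#' closed form: location = mean of log values, spread = root-mean-square
#' deviation of log values (the ML estimator, divisor n). Gamma and Weibull
#' have no closed form and are fitted numerically via
#' [fitdistrplus::fitdist()] with moment-based starting values; optimizer
#' nonconvergence is flagged in the result, not silently ignored.
#'
#' @param values Positive numeric vector with at least 3 distinct values.
#' @param family `"lognormal"`, `"gamma"` or `"weibull"`.
#' @return A [fit_result()].
#' @export
fit_unimodal <- function(values, family = c("lognormal", "gamma", "weibull")) {
  family <- match.arg(family)
  assert_positive_values(values)
  if (length(unique(values)) < 3L)
    stop_arg("need at least 3 distinct values (degenerate spread otherwise)")
  if (family == "lognormal") {
    lx <- log(values)
    mu <- mean(lx)
    sg <- sqrt(mean((lx - mu)^2))
    spec <- mixture_spec("lognormal", 1, list(c(mu, sg)))
    ll <- sum(stats::dlnorm(values, mu, sg, log = TRUE))
    return(fit_result(spec, ll, n_iter = 1L, converged = TRUE))
  }
  m <- mean(values); v <- stats::var(values)
  start <- if (family == "gamma") {
    list(shape = m^2 / v, rate = m / v)
  } else {
    # Weibull moment-flavoured start: shape from the CV of log values,
    # scale near the mean.
    list(shape = max(0.5, 1.2 / stats::sd(log(values))), scale = m)
  }
  fd <- fitdistrplus::fitdist(values, family, start = start)
  conv <- is.null(fd$convergence) || fd$convergence == 0
  est <- fd$estimate
  pars <- if (family == "gamma") c(est[["shape"]], 1 / est[["rate"]])
          else c(est[["shape"]], est[["scale"]])
  spec <- mixture_spec(family, 1, list(pars))
  fit_result(spec, fd$loglik, n_iter = 1L, converged = conv)
}

# Weighted ML for one component. Lognormal is closed form; gamma and
# Weibull maximize the weighted log-likelihood numerically starting from
# the current parameters, so each M-step can only improve on them
# (generalized EM; Nelder-Mead's returned vertex is never worse than the
# start point).
.weighted_ml <- function(values, w, family, current = NULL) {
  sw <- sum(w)
  if (family == "lognormal") {
    lx <- log(values)
    mu <- sum(w * lx) / sw
    sg <- sqrt(sum(w * (lx - mu)^2) / sw)
    return(c(mu, max(sg, 1e-8)))
  }
  df <- component_fun(family, "d")
  nll <- function(theta) {
    p <- exp(theta)
    ld <- df(values, p, log = TRUE)
    if (any(!is.finite(ld[w > 0]))) return(1e300)
    -sum(w * ld)
  }
  start <- if (!is.null(current)) log(current) else {
    m <- sum(w * values) / sw
    v <- sum(w * (values - m)^2) / sw
    if (family == "gamma") log(c(m^2 / v, v / m)) else log(c(1.2, m))
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 200))
  exp(opt$par)
}

.mixture_loglik <- function(values, spec) {
  sum(mixture_density(spec, values, log = TRUE))
}

# One EM run from an initial spec; returns a fit_result (converged flag per
# the relative-loglik criterion) or NULL if a component collapses.
.em_run <- function(values, family, init, tol, max_iter) {
  weights <- init$weights
  comps <- init$components
  df <- component_fun(family, "d")
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: responsibilities
    d1 <- weights[1] * df(values, comps[[1]])
    d2 <- weights[2] * df(values, comps[[2]])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    r1 <- d1 / tot
    # M-step
    w1 <- mean(r1)
    if (w1 < 1e-6 || w1 > 1 - 1e-6) return(NULL)  # component collapse
    comps[[1]] <- .weighted_ml(values, r1, family, comps[[1]])
    comps[[2]] <- .weighted_ml(values, 1 - r1, family, comps[[2]])
    if (comps[[1]][2] < 1e-10 || comps[[2]][2] < 1e-10) return(NULL)
    weights <- c(w1, 1 - w1)
    spec <- mixture_spec(family, weights, comps)
    ll <- .mixture_loglik(values, spec)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  fit_result(mixture_spec(family, weights, comps), trace[length(trace)],
             n_iter = it, converged = converged, loglik_trace = trace)
}

# Initial 2-component spec from a quantile split of the data.
.split_init <- function(values, family, split_q) {
  cut <- quantile_value(values, split_q)
  lo <- values[values <= cut]
  hi <- values[values > cut]
  if (length(unique(lo)) < 3L || length(unique(hi)) < 3L) return(NULL)
  f1 <- tryCatch(fit_unimodal(lo, family), error = function(e) NULL)
  f2 <- tryCatch(fit_unimodal(hi, family), error = function(e) NULL)
  if (is.null(f1) || is.null(f2)) return(NULL)
  list(weights = c(length(lo), length(hi)) / length(values),
       components = list(f1$spec$components[[1]], f2$spec$components[[1]]))
}

#' Two-component mixture fit by expectation-maximization
#'
#' Fits a two-component mixture of the given family by EM, taking the best
#' of several initializations: a deterministic split of the data at the
#' median (each half fitted unimodally, initial weights from the split
#' proportions) plus `n_restarts` seeded random quantile splits. The
#' log-likelihood is monotone non-decreasing across EM iterations (the
#' gamma/Weibull M-steps are generalized EM steps started at the current
#' parameters). Convergence is declared when the relative log-likelihood
#' change falls below `tol`. Runs in which a component collapses (weight
#' below 1e-6 or vanishing spread) are discarded; if every run collapses, a
#' degenerate-fit error is raised.
#'
#' With `k = 1` the call reduces to [fit_unimodal()].
#'
#' @param values Positive numeric vector with at least 3 distinct values.
#' @param family `"lognormal"`, `"gamma"` or `"weibull"`.
#' @param k Number of components (1 or 2).
#' @param n_restarts Random restarts in addition to the median split
#'   (default 5).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per run (default 1000).
#' @param seed Integer seed for the random restarts, or `NULL`.
#' @return A [fit_result()] with the EM iteration count and log-likelihood
#'   trace of the winning run.
#' @export
fit_mixture_em <- function(values, family = c("lognormal", "gamma", "weibull"),
                           k = 2L, n_restarts = 5L, tol = 1e-8,
                           max_iter = 1000L, seed = NULL) {
  family <- match.arg(family)
  assert_positive_values(values)
  k <- as.integer(k)
  if (k == 1L) return(fit_unimodal(values, family))
  if (k != 2L) stop_arg("only k = 1 or k = 2 supported")
  if (length(unique(values)) < 3L)
    stop_arg("need at least 3 distinct values")

  split_qs <- with_seed_or_current(seed,
    c(0.5, stats::runif(n_restarts, 0.2, 0.8)))
  best <- NULL
  for (sq in split_qs) {
    init <- .split_init(values, family, sq)
    if (is.null(init)) next
    fit <- tryCatch(.em_run(values, family, init, tol, max_iter),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop_arg("degenerate fit: every EM run collapsed a component")
  best
}

#' Rank fitted models by log-likelihood
#'
#' Stable descending sort by log-likelihood; exact ties are broken in
#' favour of the model with fewer free parameters.
#'
#' @param fits List of [fit_result()] objects fitted to the same data.
#' @return The list reordered, best fit first.
#' @export
rank_models <- function(fits) {
  if (!is.list(fits) || length(fits) == 0L)
    stop_arg("fits must be a nonempty list")
  if (length(fits) == 1L) return(fits)
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  np <- vapply(fits, function(f) n_parameters(f$spec), integer(1))
  fits[order(-ll, np)]
}
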