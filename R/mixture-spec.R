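#' Parametric distribution specification (unimodal or two-component mixture)
#'
#' A `mixture_spec` describes a concentration distribution as a one- or
#' two-component mixture of a single parametric family. Supported families
#' are the lognormal (parameters `meanlog`, `sdlog`), gamma (`shape`,
#' `scale`) and Weibull (`shape`, `scale`). These are the standard candidate
#' shapes for right-skewed, strictly positive nutrient-concentration data;
#' two lognormal components capture the typical baseflow/storm bimodality of
#' high-frequency phosphorus records.
#'
#' @param family One of `"lognormal"`, `"gamma"`, `"weibull"`.
#' @param weights Numeric vector of component probabilities (length 1 or 2);
#'   nonnegative, summing to 1.
#' @param components List of per-component parameter pairs. Lognormal
#'   components use `c(meanlog, sdlog)` (log-scale location and spread),
#'   gamma and Weibull use `c(shape, scale)`. Spread/shape/scale must be
#'   strictly positive.
#' @return An object of class `mixture_spec`.
#' @examples
#' spec <- mixture_spec("lognormal", c(0.8, 0.2),
#'                      list(c(-4.2, 0.5), c(-2.5, 0.6)))
#' mixture_mean(spec)
#' @export
mixture_spec <- function(family, weights, components) {
  family <- match.arg(family, c("lognormal", "gamma", "weibull"))
  weights <- as.numeric(weights)
  if (!is.list(components)) components <- list(components)
  k <- length(weights)
  if (k < 1L || k > 2L) stop_arg("1 or 2 components supported, got %d", k)
  if (length(components) != k)
    stop_arg("weights (%d) and components (%d) disagree in length",
             k, length(components))
  if (anyNA(weights) || any(weights < 0))
    stop_arg("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12)
    stop_arg("weights must sum to 1 (got %.15g)", sum(weights))
  components <- lapply(components, function(p) {
    p <- as.numeric(p)
    if (length(p) != 2L || anyNA(p) || !all(is.finite(p)))
      stop_arg("each component needs 2 finite parameters")
    if (p[2] <= 0) stop_arg("component spread/scale must be > 0")
    if (family != "lognormal" && p[1] <= 0)
      stop_arg("%s shape must be > 0", family)
    p
  })
  structure(list(family = family, weights = weights, components = components),
            class = "mixture_spec")
}

n_components <- function(spec) length(spec$weights)

# Number of free parameters: 2 per component plus k - 1 free weights.
n_parameters <- function(spec) 2L * n_components(spec) + n_components(spec) - 1L

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %s, %d component(s)\n", x$family,
              n_components(x)))
  for (j in seq_along(x$weights)) {
    nm <- if (x$family == "lognormal") c("meanlog", "sdlog") else
      c("shape", "scale")
    cat(sprintf("  w=%.4f  %s=%.6g  %s=%.6g\n", x$weights[j],
                nm[1], x$components[[j]][1], nm[2], x$components[[j]][2]))
  }
  invisible(x)
}

component_fun <- function(family, what) {
  switch(paste(family, what, sep = "."),
    lognormal.d = function(x, p, log = FALSE) stats::dlnorm(x, p[1], p[2], log = log),
    lognormal.p = function(q, p) stats::plnorm(q, p[1], p[2]),
    lognormal.r = function(n, p) stats::rlnorm(n, p[1], p[2]),
    gamma.d     = function(x, p, log = FALSE) stats::dgamma(x, shape = p[1], scale = p[2], log = log),
    gamma.p     = function(q, p) stats::pgamma(q, shape = p[1], scale = p[2]),
    gamma.r     = function(n, p) stats::rgamma(n, shape = p[1], scale = p[2]),
    weibull.d   = function(x, p, log = FALSE) stats::dweibull(x, shape = p[1], scale = p[2], log = log),
    weibull.p   = function(q, p) stats::pweibull(q, shape = p[1], scale = p[2]),
    weibull.r   = function(n, p) stats::rweibull(n, shape = p[1], scale = p[2]),
    stop_arg("unknown family %s", family))
}

component_mean <- function(family, p) {
  switch(family,
    lognormal = exp(p[1] + p[2]^2 / 2),
    gamma = p[1] * p[2],
    weibull = p[2] * gamma(1 + 1 / p[1]))
}

component_var <- function(family, p) {
  switch(family,
    lognormal = (exp(p[2]^2) - 1) * exp(2 * p[1] + p[2]^2),
    gamma = p[1] * p[2]^2,
    weibull = p[2]^2 * (gamma(1 + 2 / p[1]) - gamma(1 + 1 / p[1])^2))
}

#' Analytic moments and quantiles of a mixture specification
#'
#' `mixture_mean` and `mixture_var` return the closed-form mean and variance
#' of the mixture; `mixture_cdf` evaluates its distribution function and
#' `mixture_quantile` inverts it numerically.
#'
#' @param spec A [mixture_spec()].
#' @param q,p Numeric vectors of quantiles / probabilities.
#' @return Numeric vector.
#' @export
mixture_mean <- function(spec) {
  sum(spec$weights * vapply(spec$components, component_mean,
                            numeric(1), family = spec$family))
}

#' @rdname mixture_mean
#' @export
mixture_var <- function(spec) {
  mu <- vapply(spec$components, component_mean, numeric(1),
               family = spec$family)
  v <- vapply(spec$components, component_var, numeric(1),
              family = spec$family)
  m <- sum(spec$weights * mu)
  sum(spec$weights * (v + mu^2)) - m^2
}

#' @rdname mixture_mean
#' @export
mixture_cdf <- function(spec, q) {
  pf <- component_fun(spec$family, "p")
  out <- numeric(length(q))
  for (j in seq_along(spec$weights))
    out <- out + spec$weights[j] * pf(q, spec$components[[j]])
  out
}

#' @rdname mixture_mean
#' @export
mixture_quantile <- function(spec, p) {
  vapply(p, function(pp) {
    stopifnot(pp > 0, pp < 1)
    # bracket using component quantiles
    lo <- 1e-12
    hi <- 10
    while (mixture_cdf(spec, hi) < pp) hi <- hi * 10
    stats::uniroot(function(x) mixture_cdf(spec, x) - pp,
                   interval = c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

mixture_density <- function(spec, x, log = FALSE) {
  df <- component_fun(spec$family, "d")
  dens <- numeric(length(x))
  for (j in seq_along(spec$weights))
    dens <- dens + spec$weights[j] * df(x, spec$components[[j]])
  if (log) log(dens) else dens
}

# A degenerate weight vector (e.g. (1, 0)) collapses to plain component
# draws, so it consumes the same RNG stream as the single-component spec.
mixture_draw <- function(spec, n) {
  rf <- component_fun(spec$family, "r")
  if (n_components(spec) == 1L) return(rf(n, spec$components[[1]]))
  if (any(spec$weights == 1))
    return(rf(n, spec$components[[which(spec$weights == 1)]]))
  lab <- sample.int(2L, n, replace = TRUE, prob = spec$weights)
  out <- numeric(n)
  for (j in 1:2) {
    idx <- which(lab == j)
    if (length(idx)) out[idx] <- rf(length(idx), spec$components[[j]])
  }
  out
}

#' Read and write mixture specifications (JSON or YAML)
#'
#' Serializes the `family`, `weights` and `components` fields. The format is
#' chosen from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param spec A [mixture_spec()].
#' @param path File path.
#' @return `read_mixture_spec` returns a [mixture_spec()];
#'   `write_mixture_spec` returns `path` invisibly.
#' @export
write_mixture_spec <- function(spec, path) {
  obj <- list(family = spec$family, weights = spec$weights,
              components = spec$components)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_mixture_spec
#' @export
read_mixture_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  }
  comps <- obj$components
  if (is.matrix(comps)) comps <- asplit(comps, 1)
  if (!is.list(comps)) comps <- list(comps)
  comps <- lapply(comps, as.numeric)
  mixture_spec(obj$family, as.numeric(obj$weights), comps)
}
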