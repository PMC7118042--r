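#' Regulatory monitoring schemes
#'
#' A monitoring scheme is a number of grab samples per year pooled over a
#' number of years. The two standard schemes are operational monitoring
#' (`scheme_om()`, 5 samples/year x 3 years = 15) and surveillance
#' monitoring (`scheme_sm()`, 12 samples/year x 3 years = 36).
#'
#' @param name Scheme label.
#' @param samples_per_year,years Positive integers; their product (the
#'   pooled sample size n) must be at least 2.
#' @return An object of class `monitoring_scheme` with fields `name`,
#'   `samples_per_year`, `years` and `n`.
#' @export
monitoring_scheme <- function(name, samples_per_year, years = 3L) {
  samples_per_year <- as.integer(samples_per_year)
  years <- as.integer(years)
  if (is.na(samples_per_year) || samples_per_year < 1L || is.na(years) ||
      years < 1L || samples_per_year * years < 2L)
    stop_arg("scheme needs samples_per_year x years >= 2")
  structure(list(name = name, samples_per_year = samples_per_year,
                 years = years, n = samples_per_year * years),
            class = "monitoring_scheme")
}

#' @rdname monitoring_scheme
#' @export
scheme_om <- function() monitoring_scheme("OM", 5L, 3L)

#' @rdname monitoring_scheme
#' @export
scheme_sm <- function() monitoring_scheme("SM", 12L, 3L)

#' @export
print.monitoring_scheme <- function(x, ...) {
  cat(sprintf("<monitoring_scheme> %s: %d/year x %d years (n = %d)\n",
              x$name, x$samples_per_year, x$years, x$n))
  invisible(x)
}

#' Draw random low-frequency sub-samples from a population series
#'
#' Each sub-sample consists of n = samples_per_year x years values drawn
#' uniformly with replacement from the whole record, unconstrained in time
#' (no workday/hour restriction), emulating the full range of sampling
#' error a grab-sampling program could incur. `draw_subsample_matrix`
#' returns the values as an n x reps matrix (one sub-sample per column),
#' which is the efficient form for large simulation runs;
#' `draw_subsamples` wraps each column in a `subsample` object carrying its
#' source indices and replicate id.
#'
#' Replicates are filled column-by-column from a single RNG stream, so for
#' a fixed seed the first k replicates do not depend on `reps`.
#'
#' @param series A `population_series` (or numeric vector).
#' @param scheme A [monitoring_scheme()].
#' @param reps Number of replicate sub-samples (default 10000).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return `draw_subsample_matrix`: numeric matrix with attribute
#'   `indices`; `draw_subsamples`: list of `subsample` objects with fields
#'   `values`, `indices`, `scheme`, `replicate`.
#' @export
draw_subsample_matrix <- function(series, scheme, reps = 10000L, seed = NULL) {
  values <- if (inherits(series, "population_series")) series$values else series
  if (length(values) < 1L) stop_arg("series must be nonempty")
  if (!inherits(scheme, "monitoring_scheme")) stop_arg("scheme must be a monitoring_scheme")
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop_arg("reps must be >= 1")
  n <- scheme$n
  idx <- with_seed_or_current(seed,
    matrix(sample.int(length(values), n * reps, replace = TRUE),
           nrow = n, ncol = reps))
  out <- matrix(values[idx], nrow = n, ncol = reps)
  attr(out, "indices") <- idx
  attr(out, "scheme") <- scheme
  out
}

#' @rdname draw_subsample_matrix
#' @export
draw_subsamples <- function(series, scheme, reps = 10000L, seed = NULL) {
  m <- draw_subsample_matrix(series, scheme, reps, seed)
  idx <- attr(m, "indices")
  lapply(seq_len(ncol(m)), function(i)
    structure(list(values = m[, i], indices = idx[, i], scheme = scheme,
                   replicate = i), class = "subsample"))
}

#' Sample statistic of a sub-sample
#'
#' @param values Nonempty numeric vector.
#' @param which `"mean"` or `"q95"`.
#' @param type Quantile rule (see [stats::quantile()]); the package-wide
#'   default is type 7, linear interpolation of order statistics.
#' @return Scalar statistic value.
#' @export
statistic <- function(values, which = c("mean", "q95"),
                      type = q95_default_type) {
  which <- match.arg(which)
  if (length(values) == 0L) stop_arg("values must be nonempty")
  if (which == "mean") mean(values) else quantile_value(values, 0.95, type)
}

#' Sampling distribution of a statistic across sub-samples
#'
#' Container pairing the Monte-Carlo draws of a statistic with the
#' benchmark value it estimates.
#'
#' @param statistic_name `"mean"` or `"q95"`.
#' @param draws Numeric vector of statistic values across replicates.
#' @param benchmark Benchmark (population) value of the statistic; > 0.
#' @return An object of class `sampling_distribution`.
#' @export
sampling_distribution <- function(statistic_name, draws, benchmark) {
  statistic_name <- match.arg(statistic_name, c("mean", "q95"))
  if (length(draws) < 1L) stop_arg("draws must be nonempty")
  if (!is.numeric(benchmark) || benchmark <= 0)
    stop_arg("benchmark must be positive")
  structure(list(statistic = statistic_name, draws = as.numeric(draws),
                 benchmark = benchmark),
            class = "sampling_distribution")
}

#' Simulate the sampling distribution of a statistic under a scheme
#'
#' Convenience wrapper: draws `reps` sub-samples and evaluates `which` on
#' each, benchmarked against the full-record statistic.
#'
#' @inheritParams draw_subsample_matrix
#' @inheritParams statistic
#' @return A [sampling_distribution()].
#' @export
simulate_sampling_distribution <- function(series, scheme, which,
                                           reps = 10000L, seed = NULL,
                                           type = q95_default_type) {
  m <- draw_subsample_matrix(series, scheme, reps, seed)
  draws <- if (which == "mean") colMeans(m)
           else apply(m, 2L, quantile_value, p = 0.95, type = type)
  bench <- benchmark_statistics(series, type = type)[[which]]
  sampling_distribution(which, draws, bench)
}

#' Relative error of a sample statistic against its benchmark
#'
#' `(x_i - x_b) / x_b * 100`, in percent. Vectorized over `x_i`.
#'
#' @param x_i Sample statistic value(s).
#' @param x_b Benchmark statistic (> 0).
#' @return Relative error(s) in percent.
#' @export
relative_error <- function(x_i, x_b) {
  if (!is.numeric(x_b) || length(x_b) != 1L || x_b <= 0)
    stop_arg("benchmark x_b must be a positive scalar")
  (x_i - x_b) / x_b * 100
}

#' Pool per-site relative-error distributions
#'
#' Concatenates relative-error vectors from several sites without
#' reweighting, giving the expected-error distribution across comparable
#' environments.
#'
#' @param per_site_errors List of numeric vectors (percent).
#' @return Single numeric vector.
#' @export
pool_errors <- function(per_site_errors) {
  if (!is.list(per_site_errors) || length(per_site_errors) == 0L)
    stop_arg("need a nonempty list of per-site error vectors")
  unlist(per_site_errors, use.names = FALSE)
}

# Third standardized moment (raw moment ratio m3 / m2^1.5, no small-sample
# bias correction).
moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero-variance draws: skewness undefined")
    return(NaN)
  }
  mean((x - m)^3) / m2^1.5
}

#' Summary of a sampling distribution
#'
#' Bias (mean of draws minus benchmark), moment skewness, and the width of
#' the 95% highest density interval of the draws.
#'
#' @param dist A [sampling_distribution()] with at least 10 draws.
#' @return Named numeric vector `c(bias, skewness, hdi95_width)`.
#' @export
summarize_sampling <- function(dist) {
  stopifnot(inherits(dist, "sampling_distribution"))
  if (length(dist$draws) < 10L) stop_arg("need at least 10 draws")
  h <- hdi(dist$draws, 0.95)
  c(bias = mean(dist$draws) - dist$benchmark,
    skewness = moment_skewness(dist$draws),
    hdi95_width = h$upper - h$lower)
}

#' Two-sample Kolmogorov-Smirnov statistic between sampling distributions
#'
#' The supremum of the absolute difference between the two empirical CDFs,
#' used to check Monte-Carlo convergence of a sampling distribution in the
#' number of replicates.
#'
#' @param dist_a,dist_b [sampling_distribution()] objects for the same
#'   statistic.
#' @return K-S statistic in \[0, 1\].
#' @export
ks_between <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "sampling_distribution"),
            inherits(dist_b, "sampling_distribution"))
  if (dist_a$statistic != dist_b$statistic)
    stop_arg("sampling distributions are for different statistics (%s vs %s)",
             dist_a$statistic, dist_b$statistic)
  ks_statistic(dist_a$draws, dist_b$draws)
}

# sup |ECDF_a - ECDF_b| over the pooled support; handles ties exactly.
ks_statistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  max(abs(fa - fb))
}

#' Write sampling-distribution draws and summary to disk
#'
#' `write_sampling_csv` writes one draw per row; `write_sampling_summary`
#' writes a JSON object with the benchmark, bias, skewness and HDI95 width.
#'
#' @param dist A [sampling_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sampling_csv <- function(dist, path) {
  utils::write.csv(data.frame(draw = seq_along(dist$draws),
                              value = dist$draws),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sampling_csv
#' @export
write_sampling_summary <- function(dist, path) {
  s <- summarize_sampling(dist)
  jsonlite::write_json(list(statistic = dist$statistic,
                            benchmark = dist$benchmark,
                            n_draws = length(dist$draws),
                            bias = s[["bias"]],
                            skewness = s[["skewness"]],
                            hdi95_width = s[["hdi95_width"]]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
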