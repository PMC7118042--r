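#' Highest density interval of posterior draws
#'
#' The shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * N)` of the `N` draws (the sorted-window algorithm of
#' Kruschke). Ties between equally short windows are broken by the
#' lowest-start window. For a credible characterisation the draws should be
#' an (approximate) sample from the posterior.
#'
#' @param draws Numeric vector of at least 10 draws.
#' @param mass Probability mass of the interval, in (0, 1); default 0.95.
#' @return An object of class `credible_interval`: list with `lower`,
#'   `upper`, `mass`, `kind = "hdi"`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(draws) < 10L) stop_arg("hdi needs at least 10 draws")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop_arg("mass must be in (0, 1)")
  s <- sort(draws)
  N <- length(s)
  m <- ceiling(mass * N)
  if (m >= N) {
    lo <- s[1]; hi <- s[N]
  } else {
    widths <- s[m:N] - s[1:(N - m + 1L)]
    i <- which.min(widths)  # which.min takes the first (lowest-start) tie
    lo <- s[i]; hi <- s[i + m - 1L]
  }
  credible_interval(lo, hi, mass, kind = "hdi")
}

#' Central (equal-tailed) credible interval of posterior draws
#'
#' Companion to [hdi()] for sensitivity checks: the interval between the
#' (1-mass)/2 and 1-(1-mass)/2 empirical quantiles.
#'
#' @inheritParams hdi
#' @param type Quantile rule (see [stats::quantile()]).
#' @return A `credible_interval` with `kind = "central"`.
#' @export
central_interval <- function(draws, mass = 0.95, type = q95_default_type) {
  if (length(draws) < 10L) stop_arg("central_interval needs at least 10 draws")
  a <- (1 - mass) / 2
  credible_interval(quantile_value(draws, a, type),
                    quantile_value(draws, 1 - a, type),
                    mass, kind = "central")
}

#' Credible interval container
#'
#' @param lower,upper Interval endpoints (lower <= upper).
#' @param mass Probability mass in (0, 1).
#' @param kind `"hdi"` or `"central"`.
#' @return An object of class `credible_interval`.
#' @export
credible_interval <- function(lower, upper, mass = 0.95,
                              kind = c("hdi", "central")) {
  kind <- match.arg(kind)
  if (lower > upper) stop_arg("lower must be <= upper")
  if (mass <= 0 || mass >= 1) stop_arg("mass must be in (0, 1)")
  structure(list(lower = lower, upper = upper, mass = mass, kind = kind),
            class = "credible_interval")
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("<%s %.0f%%> [%.6g, %.6g] (width %.6g)\n", x$kind,
              100 * x$mass, x$lower, x$upper, x$upper - x$lower))
  invisible(x)
}

interval_width <- function(ci) ci$upper - ci$lower

interval_contains <- function(ci, x) ci$lower <= x & x <= ci$upper

#' Hit rate of credible intervals against a benchmark
#'
#' The percentage of intervals that contain the benchmark statistic
#' (inclusion closed on both endpoints). Applied to 95% posterior HDIs
#' across many sub-samples this measures how often an inference method's
#' uncertainty band covers the population value.
#'
#' @param intervals List of `credible_interval` objects.
#' @param x_b Benchmark statistic.
#' @return Percentage in \[0, 100\].
#' @export
hit_rate <- function(intervals, x_b) {
  if (length(intervals) == 0L) stop_arg("need at least one interval")
  hits <- vapply(intervals, interval_contains, logical(1), x = x_b)
  100 * mean(hits)
}

#' Relative mean bias error of posterior draws
#'
#' Mean relative deviation of the posterior draws from the benchmark, in
#' percent: `mean((x_m - x_b) / x_b) * 100`. Positive values indicate that
#' the posterior overestimates the benchmark statistic, negative values
#' underestimation.
#'
#' @param draws Numeric vector of posterior draws (nonempty).
#' @param x_b Benchmark statistic (> 0).
#' @return RMBE in percent.
#' @export
rmbe <- function(draws, x_b) {
  if (length(draws) == 0L) stop_arg("draws must be nonempty")
  if (!is.numeric(x_b) || x_b <= 0) stop_arg("benchmark must be positive")
  mean((draws - x_b) / x_b) * 100
}

#' Second-order uncertainty summary across sub-samples
#'
#' Aggregates per-sub-sample posterior summaries into the hit rate and the
#' 2.5%/median/97.5% quantiles of the HDI95 widths and of the RMBE values.
#'
#' @param intervals List of `credible_interval` objects, one per
#'   sub-sample (at least 40 for meaningful tail quantiles).
#' @param rmbe_values Numeric vector of per-sub-sample RMBE values
#'   (percent), same length as `intervals`.
#' @param x_b Benchmark statistic.
#' @param type Quantile rule for the summary quantiles.
#' @return An object of class `second_order_summary`: list with
#'   `hit_rate` (percent), `hdi_width` and `rmbe` (each a named triple
#'   `q2.5`, `median`, `q97.5`), and `n`.
#' @export
summarize_second_order <- function(intervals, rmbe_values, x_b,
                                   type = q95_default_type) {
  if (length(intervals) < 40L)
    stop_arg("need at least 40 sub-samples for tail quantiles")
  if (length(rmbe_values) != length(intervals))
    stop_arg("intervals and rmbe_values lengths differ")
  widths <- vapply(intervals, interval_width, numeric(1))
  triple <- function(x) {
    q <- quantile_value(x, c(0.025, 0.5, 0.975), type = type)
    c(q2.5 = q[1], median = q[2], q97.5 = q[3])
  }
  structure(list(hit_rate = hit_rate(intervals, x_b),
                 hdi_width = triple(widths),
                 rmbe = triple(rmbe_values),
                 n = length(intervals)),
            class = "second_order_summary")
}

#' @export
print.second_order_summary <- function(x, ...) {
  cat(sprintf("<second_order_summary> n = %d sub-samples\n", x$n))
  cat(sprintf("  hit rate: %.1f%%\n", x$hit_rate))
  cat(sprintf("  HDI95 width [2.5%% med 97.5%%]: %.3g %.3g %.3g mg P/L\n",
              x$hdi_width[1], x$hdi_width[2], x$hdi_width[3]))
  cat(sprintf("  RMBE     [2.5%% med 97.5%%]: %.3g %.3g %.3g %%\n",
              x$rmbe[1], x$rmbe[2], x$rmbe[3]))
  invisible(x)
}

#' Serialize a second-order summary to JSON or CSV
#'
#' JSON carries named fields; CSV writes one row with hit rate (%), the
#' HDI95 width quantiles (mg P/L) and the RMBE quantiles (%).
#'
#' @param summary A `second_order_summary`.
#' @param path Output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_second_order <- function(summary, path) {
  row <- c(hit_rate = summary$hit_rate,
           stats::setNames(summary$hdi_width,
                           paste0("hdi_width_", c("q2.5", "median", "q97.5"))),
           stats::setNames(summary$rmbe,
                           paste0("rmbe_", c("q2.5", "median", "q97.5"))),
           n = summary$n)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(as.data.frame(as.list(row)), path, row.names = FALSE)
  } else {
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
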