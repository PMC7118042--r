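#' Physicochemical status classes
#'
#' The three-class High/Good/Moderate scheme used for nutrient
#' concentrations in rivers, as an ordered factor with
#' Moderate < Good < High. (Poor/Bad classes of the wider five-class
#' ecological scheme are not assessed by the mean/95th-percentile rule and
#' are out of scope.)
#'
#' @param x Character vector of class names.
#' @return Ordered factor with levels Moderate < Good < High.
#' @export
status_class <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("Moderate", "Good", "High"))
  if (length(bad)) stop_arg("unknown status class: %s", paste(bad, collapse = ", "))
  factor(x, levels = c("Moderate", "Good", "High"), ordered = TRUE)
}

#' Status class boundaries for a water-quality variable
#'
#' Upper concentration bounds of the High and Good classes, separately for
#' the mean and the 95th percentile. The defaults are the Irish river
#' boundaries for total reactive phosphorus: mean High <= 0.025,
#' Good (0.025, 0.035], Moderate > 0.035 mg P/L; 95th percentile
#' High <= 0.045, Good (0.045, 0.075], Moderate > 0.075 mg P/L. Boundary
#' values belong to the better class.
#'
#' @param mean_high,mean_good Upper bounds of High and Good for the mean.
#' @param q95_high,q95_good Upper bounds of High and Good for the 95th
#'   percentile.
#' @return An object of class `class_boundaries`.
#' @export
class_boundaries <- function(mean_high = 0.025, mean_good = 0.035,
                             q95_high = 0.045, q95_good = 0.075) {
  for (v in c(mean_high, mean_good, q95_high, q95_good))
    if (!is.numeric(v) || v <= 0) stop_arg("boundaries must be positive")
  if (mean_high >= mean_good || q95_high >= q95_good)
    stop_arg("High upper bound must be below Good upper bound")
  structure(list(mean = c(high = mean_high, good = mean_good),
                 q95 = c(high = q95_high, good = q95_good)),
            class = "class_boundaries")
}

#' Read class boundaries from YAML or JSON
#'
#' Expects keys `mean_high`, `mean_good`, `q95_high`, `q95_good` (units
#' mg P/L).
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return A [class_boundaries()] object.
#' @export
read_class_boundaries <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  class_boundaries(obj$mean_high, obj$mean_good, obj$q95_high, obj$q95_good)
}

#' Classify one statistic against class boundaries
#'
#' @param value Statistic value in mg P/L (strictly positive).
#' @param which `"mean"` or `"q95"`.
#' @param boundaries A [class_boundaries()].
#' @return A one-element [status_class()] factor.
#' @export
classify_statistic <- function(value, which = c("mean", "q95"),
                               boundaries = class_boundaries()) {
  which <- match.arg(which)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0)
    stop_arg("value must be a single positive concentration")
  b <- boundaries[[which]]
  cls <- if (value <= b[["high"]]) "High"
         else if (value <= b[["good"]]) "Good"
         else "Moderate"
  status_class(cls)
}

#' Combine per-statistic classes into one river status
#'
#' The status is High when either the mean or the 95th percentile is High,
#' Moderate only when both statistics are Moderate, and Good otherwise.
#'
#' @param mean_class,q95_class [status_class()] values.
#' @return A one-element [status_class()] factor.
#' @export
combine_status <- function(mean_class, q95_class) {
  m <- as.character(mean_class); q <- as.character(q95_class)
  cls <- if (m == "High" || q == "High") "High"
         else if (m == "Moderate" && q == "Moderate") "Moderate"
         else "Good"
  status_class(cls)
}

#' Face-value status classification
#'
#' Classifies directly from the raw sample mean and sample 95th percentile,
#' with no treatment of sampling uncertainty.
#'
#' @param sample Numeric vector of concentrations.
#' @param boundaries A [class_boundaries()].
#' @param type Quantile rule for the sample 95th percentile.
#' @return A one-element [status_class()] factor.
#' @export
face_value_status <- function(sample, boundaries = class_boundaries(),
                              type = q95_default_type) {
  assert_positive_values(sample, "sample")
  combine_status(
    classify_statistic(mean(sample), "mean", boundaries),
    classify_statistic(quantile_value(sample, 0.95, type = type), "q95",
                       boundaries))
}

# One-sided test of "the population mean exceeds boundary b":
# t = (xbar - b) / (s / sqrt(n)) against t_{1-alpha, n-1}.
.t_stat_mean <- function(sample, b) {
  n <- length(sample)
  (mean(sample) - b) / (stats::sd(sample) / sqrt(n))
}

# Approximate one-sided test of "the lognormal 95th percentile exceeds b",
# on the log scale. The percentile estimator mlog + z*slog is approximately
# normal with variance slog^2 * (1/n + z^2/(2(n-1))); the standardized
# statistic is referred to the t distribution with n-1 df.
.t_stat_q95_lognormal <- function(sample, b) {
  n <- length(sample)
  lx <- log(sample)
  mlog <- mean(lx); slog <- stats::sd(lx)
  z <- z95()
  (mlog + z * slog - log(b)) / (slog * sqrt(1 / n + z^2 / (2 * (n - 1))))
}

# Nonparametric alternative: binomial test on the count of observations
# above b (population exceedance probability p0 = 0.05).
.binom_exceeds <- function(sample, b, alpha, tail) {
  n <- length(sample); k <- sum(sample > b)
  if (tail == "right") {
    stats::pbinom(k - 1, n, 0.05, lower.tail = FALSE) < alpha  # P(K >= k)
  } else {
    stats::pbinom(k, n, 0.05) < alpha                          # P(K <= k)
  }
}

#' Status classification by one-sided t tests against class boundaries
#'
#' The right-tailed ("benefit-of-doubt") variant starts from High and
#' down-grades a statistic only when it is significantly *above* a class
#' boundary at level `alpha`; this is the scheme used by several EU
#' regulators at a 99% confidence level. The left-tailed ("fail-safe")
#' variant mirrors it: it starts from Moderate and up-grades only when the
#' statistic is significantly *below* the boundary. The sample mean is
#' tested with the one-sample t statistic. For the 95th percentile no
#' standard regulatory construction exists; the default tests the lognormal
#' percentile on the log scale (`q95_method = "lognormal"`, an approximate
#' t test for a lognormal quantile), with a nonparametric binomial
#' exceedance-count test available as `q95_method = "binomial"`. Per-
#' statistic classes are combined with [combine_status()].
#'
#' @param sample Numeric vector of concentrations (n >= 3, positive spread).
#' @param boundaries A [class_boundaries()].
#' @param alpha One-sided significance level (default 0.01, i.e. 99%
#'   confidence).
#' @param tail `"right"` (benefit-of-doubt, default) or `"left"`
#'   (fail-safe).
#' @param q95_method `"lognormal"` (default) or `"binomial"`; see Details.
#' @return A one-element [status_class()] factor.
#' @export
t_test_status <- function(sample, boundaries = class_boundaries(),
                          alpha = 0.01, tail = c("right", "left"),
                          q95_method = c("lognormal", "binomial")) {
  tail <- match.arg(tail)
  q95_method <- match.arg(q95_method)
  assert_positive_values(sample, "sample")
  n <- length(sample)
  if (n < 3L) stop_arg("t-test classification needs n >= 3")
  if (stats::sd(sample) == 0) stop_arg("degenerate sample: zero spread")
  tcrit <- stats::qt(1 - alpha, df = n - 1)

  sig_above <- function(which, b) {
    if (which == "mean") .t_stat_mean(sample, b) > tcrit
    else if (q95_method == "lognormal") .t_stat_q95_lognormal(sample, b) > tcrit
    else .binom_exceeds(sample, b, alpha, "right")
  }
  sig_below <- function(which, b) {
    if (which == "mean") .t_stat_mean(sample, b) < -tcrit
    else if (q95_method == "lognormal") .t_stat_q95_lognormal(sample, b) < -tcrit
    else .binom_exceeds(sample, b, alpha, "left")
  }

  classify_one <- function(which) {
    b <- boundaries[[which]]
    if (tail == "right") {
      # best class not significantly excluded
      if (sig_above(which, b[["good"]])) "Moderate"
      else if (sig_above(which, b[["high"]])) "Good"
      else "High"
    } else {
      # worst class not significantly excluded
      if (sig_below(which, b[["high"]])) "High"
      else if (sig_below(which, b[["good"]])) "Good"
      else "Moderate"
    }
  }
  combine_status(status_class(classify_one("mean")),
                 status_class(classify_one("q95")))
}

#' Posterior class probabilities from paired posterior draws
#'
#' Monte-Carlo evaluation of the posterior probability of each status class
#' from paired posterior draws of the mean and the 95th percentile:
#' P(High) is the fraction of draws where either statistic falls in its
#' High class, P(Moderate) the fraction where both fall in Moderate, and
#' P(Good) the remaining three cells (Good,Good), (Good,Moderate),
#' (Moderate,Good). The three probabilities partition the draws and sum to
#' 1 exactly.
#'
#' @param posterior A [posterior_draws] object (paired draws), or a list
#'   with numeric fields `draws_mean` and `draws_q95` of equal length.
#' @param boundaries A [class_boundaries()].
#' @return An object of class `class_probabilities`: named numeric
#'   `c(High = ..., Good = ..., Moderate = ...)`.
#' @export
bayes_class_probabilities <- function(posterior,
                                      boundaries = class_boundaries()) {
  dm <- posterior$draws_mean; dq <- posterior$draws_q95
  if (is.null(dm) || is.null(dq) || length(dm) != length(dq))
    stop_arg("posterior must carry paired draws_mean / draws_q95 of equal length")
  if (!is.null(posterior$paired) && !isTRUE(posterior$paired))
    stop_arg("posterior draws must be paired")
  N <- length(dm)
  bm <- boundaries$mean; bq <- boundaries$q95
  mean_high <- dm <= bm[["high"]]
  mean_mod  <- dm > bm[["good"]]
  q95_high  <- dq <= bq[["high"]]
  q95_mod   <- dq > bq[["good"]]
  n_high <- sum(mean_high | q95_high)
  n_mod  <- sum(mean_mod & q95_mod & !(mean_high | q95_high))
  p <- c(High = n_high, Good = N - n_high - n_mod, Moderate = n_mod) / N
  structure(p, class = "class_probabilities")
}

#' @export
print.class_probabilities <- function(x, ...) {
  cat(sprintf("P(High) = %.3f  P(Good) = %.3f  P(Moderate) = %.3f\n",
              x[["High"]], x[["Good"]], x[["Moderate"]]))
  invisible(x)
}

#' Misgrading frequencies relative to a benchmark status
#'
#' @param assigned A [status_class()] factor (or character vector) of
#'   statuses assigned from sub-samples.
#' @param benchmark The benchmark ("correct") status.
#' @return Named numeric vector of percentages
#'   `c(correct = ..., over = ..., under = ...)` summing to 100; `over`
#'   counts assignments better than the benchmark, `under` worse.
#' @export
misgrade_frequency <- function(assigned, benchmark) {
  assigned <- status_class(assigned)
  benchmark <- status_class(as.character(benchmark))
  if (length(assigned) == 0L) stop_arg("assigned must be nonempty")
  100 * c(correct = mean(assigned == benchmark),
          over = mean(assigned > benchmark),
          under = mean(assigned < benchmark))
}
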