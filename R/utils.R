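# Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code)
  }
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_positive_values <- function(values, what = "values") {
  if (length(values) == 0L) stop_arg("%s must be nonempty", what)
  if (anyNA(values)) stop_arg("%s must not contain NA", what)
  if (any(values <= 0)) stop_arg("%s must be strictly positive", what)
  invisible(values)
}

# One quantile convention shared by every module: linear interpolation of
# order statistics (stats::quantile type 7) by default; type 1 gives the
# discrete (non-interpolated) order-statistic rule.
q95_default_type <- 7L

quantile_value <- function(values, p, type = q95_default_type) {
  unname(stats::quantile(values, probs = p, type = type, names = FALSE))
}

# Standard normal 95% quantile used for lognormal percentile formulas.
z95 <- function() stats::qnorm(0.95)
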