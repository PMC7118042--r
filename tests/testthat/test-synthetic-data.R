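test_that("mixture_spec validates weights and parameters", {
  expect_s3_class(mixture_spec("lognormal", c(0.7, 0.3),
                               list(c(-4, 0.5), c(-2, 0.6))), "mixture_spec")
  expect_error(mixture_spec("lognormal", c(0.7, 0.2),
                            list(c(-4, 0.5), c(-2, 0.6))), "sum to 1")
  expect_error(mixture_spec("lognormal", c(-0.1, 1.1),
                            list(c(-4, 0.5), c(-2, 0.6))), "nonnegative")
  expect_error(mixture_spec("lognormal", 1, list(c(-4, 0))), "spread")
  expect_error(mixture_spec("gamma", 1, list(c(-1, 2))), "shape")
  expect_error(mixture_spec("lognormal", c(0.5, 0.3, 0.2),
                            list(c(-4, 1), c(-3, 1), c(-2, 1))), "components")
})

test_that("degenerate mixture weights (1, 0) reproduce single-component draws", {
  spec2 <- mixture_spec("lognormal", c(1, 0), list(c(-3.5, 0.5), c(-2, 0.6)))
  spec1 <- mixture_spec("lognormal", 1, list(c(-3.5, 0.5)))
  p2 <- generate_population(spec2, 500, seed = 7)
  p1 <- generate_population(spec1, 500, seed = 7)
  expect_identical(p2$values, p1$values)
  expect_equal(mixture_mean(spec2), mixture_mean(spec1))
  expect_equal(mixture_cdf(spec2, c(0.01, 0.05)),
               mixture_cdf(spec1, c(0.01, 0.05)))
})

test_that("empirical moments of mixture draws match analytic moments", {
  for (nm in preset_names()) {
    spec <- preset_scenario(nm)$spec
    pop <- generate_population(spec, 1e6, seed = 123)
    mu <- mixture_mean(spec)
    v <- mixture_var(spec)
    se_mean <- sqrt(v / 1e6)
    expect_lt(abs(mean(pop$values) - mu), 4 * se_mean)
    # variance MC standard error ~ sqrt((m4 - v^2)/n); bound loosely via
    # 4th moment of draws
    m4 <- mean((pop$values - mean(pop$values))^4)
    se_var <- sqrt((m4 - v^2) / 1e6)
    expect_lt(abs(var(pop$values) - v), 4 * se_var)
  }
})

test_that("closed-form lognormal mean is recovered at one million draws", {
  spec <- mixture_spec("lognormal", 1, list(c(-3.5, 0.5)))
  pop <- generate_population(spec, 1e6, seed = 99)
  truth <- exp(-3.5 + 0.5^2 / 2)
  se <- sqrt(mixture_var(spec) / 1e6)
  expect_lt(abs(mean(pop$values) - truth), 3 * se)
})

test_that("generation is seed-deterministic and censoring is a floor substitution", {
  spec <- preset_scenario("good_near_boundary")$spec
  a <- generate_population(spec, 1000, seed = 5)
  b <- generate_population(spec, 1000, seed = 5)
  expect_identical(a$values, b$values)
  cns <- generate_population(spec, 5000, seed = 5, censor_at = 0.003)
  expect_gte(min(cns$values), 0.003)
  # censoring substitutes, never removes
  expect_length(cns$values, 5000)
  raw <- generate_population(spec, 5000, seed = 5)
  expect_identical(cns$values[raw$values >= 0.003],
                   raw$values[raw$values >= 0.003])
})

test_that("generate_population rejects invalid arguments", {
  spec <- preset_scenario("unimodal_lognormal")$spec
  expect_error(generate_population(spec, 0), "n_hours")
  expect_error(generate_population(list(), 10), "mixture_spec")
})

test_that("benchmark_statistics follows the shared quantile convention", {
  expect_equal(benchmark_statistics(population_series(rep(0.02, 50))),
               c(mean = 0.02, q95 = 0.02))
  expect_equal(benchmark_statistics(population_series(1:100))[["q95"]], 95.05)
  expect_equal(benchmark_statistics(population_series(0.07)),
               c(mean = 0.07, q95 = 0.07))
  expect_error(benchmark_statistics(numeric(0)), "nonempty")
})

test_that("every preset's large-population status matches its intended class", {
  for (nm in preset_names()) {
    preset <- preset_scenario(nm)
    for (seed in 1:10) {
      pop <- generate_population(preset$spec, 2e5, seed = seed)
      b <- benchmark_statistics(pop)
      got <- combine_status(classify_statistic(b[["mean"]], "mean"),
                            classify_statistic(b[["q95"]], "q95"))
      expect_identical(as.character(got),
                       as.character(preset$intended_benchmark_class),
                       label = sprintf("%s seed %d status", nm, seed))
    }
  }
  expect_error(preset_scenario("nope"), "unknown preset")
})

test_that("good_near_boundary mean sits in the narrow good class", {
  p <- preset_scenario("good_near_boundary")
  expect_gt(p$analytic_mean, 0.025)
  expect_lte(p$analytic_mean, 0.035)
  m <- preset_scenario("moderate_far")
  expect_gt(m$analytic_mean, 0.035)
  expect_gt(m$analytic_q95, 0.075)
  expect_identical(n_components(preset_scenario("unimodal_lognormal")$spec), 1L)
})

test_that("series CSV writer round-trips through the reader", {
  pop <- generate_population(preset_scenario("moderate_far")$spec, 48, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(pop, path)
  expect_identical(readLines(path, n = 1), "timestamp,concentration_mgP_L")
  back <- read_series_csv(path)
  expect_equal(back$values, pop$values)
  expect_equal(back$timestamps, pop$timestamps)
})

test_that("mixture spec serialization round-trips in JSON and YAML", {
  spec <- preset_scenario("good_near_boundary")$spec
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mixture_spec(spec, path)
    back <- read_mixture_spec(path)
    expect_identical(back$family, spec$family)
    expect_equal(back$weights, spec$weights)
    expect_equal(back$components, spec$components)
  }
})
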