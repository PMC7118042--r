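test_that("monitoring schemes encode the regulatory sample sizes", {
  expect_identical(scheme_om()$n, 15L)
  expect_identical(scheme_sm()$n, 36L)
  expect_error(monitoring_scheme("X", 1, 1), ">= 2")
})

test_that("draw_subsamples yields reps sub-samples of scheme size, seeded", {
  pop <- generate_population(preset_scenario("moderate_far")$spec, 5000,
                             seed = 1)
  subs <- draw_subsamples(pop, scheme_om(), reps = 50, seed = 9)
  expect_length(subs, 50)
  expect_true(all(vapply(subs, function(s) length(s$values), integer(1)) == 15L))
  expect_true(all(vapply(subs, function(s)
    all(s$values == pop$values[s$indices]), logical(1))))
  again <- draw_subsamples(pop, scheme_om(), reps = 50, seed = 9)
  expect_identical(lapply(subs, `[[`, "indices"),
                   lapply(again, `[[`, "indices"))
  # constant population -> every sub-sample constant
  const <- population_series(rep(0.05, 100))
  m <- draw_subsample_matrix(const, scheme_sm(), reps = 10, seed = 1)
  expect_true(all(m == 0.05))
})

test_that("early replicates are unchanged when reps grows", {
  pop <- generate_population(preset_scenario("moderate_far")$spec, 5000,
                             seed = 1)
  small <- draw_subsample_matrix(pop, scheme_om(), reps = 20, seed = 4)
  big <- draw_subsample_matrix(pop, scheme_om(), reps = 200, seed = 4)
  expect_identical(small[, 1:20], big[, 1:20], )
})

test_that("statistic applies the configured quantile rule", {
  expect_equal(statistic(c(2, 4, 6), "mean"), 4)
  expect_equal(statistic(1:100, "q95"), 95.05)
  expect_equal(statistic(1:100, "q95", type = 1), 95)
  expect_equal(statistic(0.042, "q95"), 0.042)
  expect_error(statistic(numeric(0), "mean"), "nonempty")
})

test_that("relative error follows (x_i - x_b)/x_b * 100", {
  expect_equal(relative_error(0.05, 0.05), 0)
  expect_equal(relative_error(0.1, 0.05), 100)
  expect_equal(relative_error(0, 0.05), -100)
  expect_error(relative_error(0.1, 0), "positive")
})

test_that("pool_errors concatenates sites without reweighting", {
  a <- rnorm(100); b <- rnorm(50); c <- rnorm(25)
  expect_identical(pool_errors(list(a)), a)
  expect_identical(pool_errors(list(a, b, c)), c(a, b, c))
  expect_length(pool_errors(list(rnorm(10000), rnorm(10000), rnorm(10000))),
                30000L)
  expect_error(pool_errors(list()), "nonempty")
})

test_that("summarize_sampling matches hand-computed moments", {
  d <- sampling_distribution("mean", rep(0.05, 20), 0.05)
  expect_warning(s <- summarize_sampling(d), "skewness undefined")
  expect_equal(s[["bias"]], 0)
  expect_equal(s[["hdi95_width"]], 0)
  expect_true(is.nan(s[["skewness"]]))

  # skewness of {0,0,0,1}: m3/m2^1.5 = 1.1547 (hand moment computation)
  skew_0001 <- wqbench:::moment_skewness(c(0, 0, 0, 1))
  expect_equal(skew_0001, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(skew_0001, 1.1547, tolerance = 1e-4)

  sym <- sampling_distribution("mean", rep(c(1, 2, 3), 100), 2)
  expect_equal(summarize_sampling(sym)[["skewness"]], 0, tolerance = 1e-12)
})

test_that("K-S statistic equals the ECDF sup-difference", {
  da <- sampling_distribution("mean", c(1, 2, 3), 2)
  db <- sampling_distribution("mean", c(1, 2, 4), 2)
  expect_equal(ks_between(da, da), 0)
  expect_equal(ks_between(da, db), 1 / 3)
  disjoint <- sampling_distribution("mean", c(10, 11, 12), 11)
  expect_equal(ks_between(da, disjoint), 1)
  dq <- sampling_distribution("q95", c(1, 2, 3), 2)
  expect_error(ks_between(da, dq), "different statistics")
  # agreement with stats::ks.test on continuous data
  withr::with_seed(8, {
    x <- rlnorm(500); y <- rlnorm(400, 0.2)
  })
  expect_equal(ks_between(sampling_distribution("mean", x, 1),
                          sampling_distribution("mean", y, 1)),
               unname(suppressWarnings(ks.test(x, y)$statistic)))
})

test_that("sub-sample means are unbiased for the population mean", {
  pop <- generate_population(preset_scenario("good_near_boundary")$spec,
                             26280, seed = 77)
  d <- simulate_sampling_distribution(pop, scheme_om(), "mean",
                                      reps = 10000, seed = 78)
  tol <- 4 * sd(pop$values) / sqrt(10000 * 15)
  expect_lt(abs(mean(d$draws) - d$benchmark), tol)
})

test_that("q95 sampling distributions are more right-skewed than the mean's and relax from OM to SM", {
  for (preset in c("good_near_boundary", "moderate_far")) {
    sk <- array(NA_real_, c(10, 2, 2),
                dimnames = list(NULL, c("mean", "q95"), c("OM", "SM")))
    for (seed in 1:10) {
      pop <- generate_population(preset_scenario(preset)$spec, 26280,
                                 seed = seed)
      for (sch in list(scheme_om(), scheme_sm()))
        for (w in c("mean", "q95"))
          sk[seed, w, sch$name] <- summarize_sampling(
            simulate_sampling_distribution(pop, sch, w, reps = 5000,
                                           seed = seed + 1000))[["skewness"]]
    }
    # increasing the sample size from OM to SM damps the skew, per seed
    for (w in c("mean", "q95"))
      expect_true(all(sk[, w, "OM"] > sk[, w, "SM"]),
                  label = sprintf("%s %s OM > SM", preset, w))
    # the 95th percentile is the more skewed statistic (across-seed
    # average; individual finite populations are noisy in the far tail)
    for (sch in c("OM", "SM"))
      expect_gt(mean(sk[, "q95", sch]), mean(sk[, "mean", sch]),
                label = sprintf("%s q95 vs mean under %s", preset, sch))
  }
})

test_that("sampling distribution CSV and summary JSON are written", {
  d <- sampling_distribution("mean", seq(0.01, 0.1, length.out = 100), 0.05)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sampling_csv(d, csv)
  expect_equal(nrow(read.csv(csv)), 100)
  write_sampling_summary(d, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$benchmark, 0.05)
  expect_equal(back$bias, mean(d$draws) - 0.05)
})
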