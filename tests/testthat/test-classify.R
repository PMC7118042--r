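test_that("boundary values belong to the better class", {
  expect_identical(as.character(classify_statistic(0.025, "mean")), "High")
  expect_identical(as.character(classify_statistic(0.0251, "mean")), "Good")
  expect_identical(as.character(classify_statistic(0.035, "mean")), "Good")
  expect_identical(as.character(classify_statistic(0.0351, "mean")), "Moderate")
  expect_identical(as.character(classify_statistic(0.045, "q95")), "High")
  expect_identical(as.character(classify_statistic(0.0451, "q95")), "Good")
  expect_identical(as.character(classify_statistic(0.075, "q95")), "Good")
  expect_identical(as.character(classify_statistic(0.0751, "q95")), "Moderate")
  expect_error(classify_statistic(0, "mean"), "positive")
})

test_that("combine_status follows the 9-cell truth table", {
  cells <- expand.grid(m = c("High", "Good", "Moderate"),
                       q = c("High", "Good", "Moderate"),
                       stringsAsFactors = FALSE)
  want <- apply(cells, 1, function(r) {
    if (r[["m"]] == "High" || r[["q"]] == "High") "High"
    else if (r[["m"]] == "Moderate" && r[["q"]] == "Moderate") "Moderate"
    else "Good"
  })
  got <- apply(cells, 1, function(r)
    as.character(combine_status(status_class(r[["m"]]),
                                status_class(r[["q"]]))))
  expect_identical(got, want)
  # spot checks of the union / intersection events
  expect_identical(as.character(combine_status(status_class("High"),
                                               status_class("Moderate"))),
                   "High")
  expect_identical(as.character(combine_status(status_class("Good"),
                                               status_class("Moderate"))),
                   "Good")
  expect_identical(as.character(combine_status(status_class("Moderate"),
                                               status_class("Moderate"))),
                   "Moderate")
})

test_that("face_value_status classifies from the raw sample statistics", {
  # constant-ish samples pin both statistics
  expect_identical(as.character(face_value_status(rep(c(0.019, 0.021), 10))),
                   "High")
  expect_identical(as.character(face_value_status(rep(0.10, 10))), "Moderate")
  # mean 0.030, q95 0.060 -> Good: build a sample with those statistics
  s <- c(rep(0.025, 18), 0.055, 0.061)  # mean 0.0283, q95 type-7 ~ 0.0604
  expect_identical(as.character(face_value_status(s)), "Good")
})

test_that("custom boundaries are honoured and readable from YAML/JSON", {
  b <- class_boundaries(0.1, 0.2, 0.3, 0.4)
  expect_identical(as.character(classify_statistic(0.15, "mean", b)), "Good")
  expect_error(class_boundaries(0.2, 0.1, 0.3, 0.4), "below")
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    obj <- list(mean_high = 0.025, mean_good = 0.035,
                q95_high = 0.045, q95_good = 0.075)
    if (ext == ".yaml") yaml::write_yaml(obj, path)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE)
    bb <- read_class_boundaries(path)
    expect_equal(bb$mean[["good"]], 0.035)
    expect_equal(bb$q95[["high"]], 0.045)
  }
})

test_that("t-test classification gives benefit of doubt on the right tail", {
  # far below all boundaries with tiny spread: High under both tails
  withr::with_seed(41, low <- rlnorm(15, log(0.005), 0.05))
  expect_identical(as.character(t_test_status(low, tail = "right")), "High")
  expect_identical(as.character(t_test_status(low, tail = "left")), "High")
  # sample mean slightly above the good/moderate boundary with large
  # spread: the right tail cannot reject, so the class is at least the
  # face-value class
  withr::with_seed(42, s <- rlnorm(15, log(0.036), 1))
  fv <- face_value_status(s)
  rt <- t_test_status(s, tail = "right")
  expect_gte(as.integer(rt), as.integer(fv))
  # mean exactly at a boundary: t = 0 is never significant
  sym <- rep(c(0.024, 0.026), 8)  # mean exactly 0.025
  expect_identical(as.character(t_test_status(sym, tail = "right")), "High")
  expect_error(t_test_status(rep(0.02, 10)), "zero spread")
  expect_error(t_test_status(c(0.02, 0.03)), "n >= 3")
})

test_that("right-tail dominates face value; left tail is dominated (1000 random samples)", {
  withr::with_seed(43, {
    for (i in 1:1000) {
      n <- sample(c(5, 15, 36), 1)
      s <- rlnorm(n, runif(1, -5, -2), runif(1, 0.1, 1.5))
      fv <- as.integer(face_value_status(s))
      rt <- as.integer(t_test_status(s, tail = "right"))
      lt <- as.integer(t_test_status(s, tail = "left"))
      expect_gte(rt, fv)
      expect_lte(lt, fv)
    }
  })
})

test_that("binomial exceedance q95 test is available and sane", {
  withr::with_seed(44, s <- rlnorm(36, log(0.2), 0.3))  # far into Moderate
  expect_identical(
    as.character(t_test_status(s, tail = "right", q95_method = "binomial")),
    as.character(t_test_status(s, tail = "right", q95_method = "lognormal")))
})

test_that("bayes class probabilities partition to exactly one", {
  # brute-force 4-draw example: (H,G), (G,G), (G,M), (M,M)
  post <- list(draws_mean = c(0.02, 0.03, 0.03, 0.04),
               draws_q95 = c(0.06, 0.06, 0.08, 0.08), paired = TRUE)
  p <- bayes_class_probabilities(post)
  expect_equal(unname(p[["High"]]), 0.25)
  expect_equal(unname(p[["Good"]]), 0.5)
  expect_equal(unname(p[["Moderate"]]), 0.25)
  expect_identical(sum(p), 1)
  # all draws in (Good, Good)
  gg <- list(draws_mean = rep(0.03, 100), draws_q95 = rep(0.06, 100),
             paired = TRUE)
  expect_equal(as.numeric(bayes_class_probabilities(gg)), c(0, 1, 0))
  # degenerate one-hot for a point mass in one cell
  mm <- list(draws_mean = rep(0.2, 100), draws_q95 = rep(0.2, 100),
             paired = TRUE)
  expect_equal(as.numeric(bayes_class_probabilities(mm)), c(0, 0, 1))
  expect_error(bayes_class_probabilities(
    list(draws_mean = 1:3, draws_q95 = 1:4, paired = TRUE)), "equal length")
})

test_that("probabilities sum to one exactly for arbitrary paired draws", {
  withr::with_seed(45, {
    for (i in 1:50) {
      N <- sample(100:500, 1)
      post <- list(draws_mean = rlnorm(N, runif(1, -4.5, -2), 0.5),
                   draws_q95 = rlnorm(N, runif(1, -4, -1.5), 0.5),
                   paired = TRUE)
      p <- bayes_class_probabilities(post)
      expect_identical(sum(p), 1)
      expect_true(all(p >= 0 & p <= 1))
    }
  })
})

test_that("point-mass posteriors reproduce the face-value status", {
  withr::with_seed(46, s <- rlnorm(36, -3.4, 0.6))
  fv <- as.character(face_value_status(s))
  pm <- list(draws_mean = rep(mean(s), 200),
             draws_q95 = rep(unname(quantile(s, 0.95, type = 7)), 200),
             paired = TRUE)
  p <- bayes_class_probabilities(pm)
  expect_equal(unname(p[[fv]]), 1)
  expect_identical(names(p)[which.max(p)], fv)
})

test_that("misgrade_frequency counts over- and under-grading", {
  expect_equal(misgrade_frequency(rep("Good", 10), "Good"),
               c(correct = 100, over = 0, under = 0))
  expect_equal(misgrade_frequency(c("High", "Good", "Moderate", "Good"),
                                  "Good"),
               c(correct = 50, over = 25, under = 25))
  got <- misgrade_frequency(c("High", "Good", "Moderate"), "High")
  expect_equal(unname(got[["over"]]), 0)
  expect_equal(sum(got), 100)
  # permutation invariance
  x <- c("High", "High", "Good", "Moderate", "Good")
  expect_equal(misgrade_frequency(x, "Good"),
               misgrade_frequency(rev(x), "Good"))
})
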