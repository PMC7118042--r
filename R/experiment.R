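#' Experiment configuration
#'
#' Bundles every knob of the benchmarking experiment: which populations to
#' analyse (scenario presets and/or CSV files), the monitoring schemes, the
#' number of sub-sample replicates and posterior draws, the inference /
#' classification methods, the quantile rule, the prior box, and the
#' significance level. The defaults mirror standard regulatory benchmarking
#' practice: 10,000 replicates, OM 5x3 and SM 12x3 schemes, 1000 posterior
#' draws, alpha = 0.01.
#'
#' @param presets Character vector of [preset_scenario()] names.
#' @param csv_paths Optional character vector of population CSV files
#'   (format of [write_series_csv()]); read with [read_series_csv()].
#' @param schemes List of [monitoring_scheme()] objects.
#' @param reps Sub-sample replicates per population x scheme.
#' @param n_draws Posterior draws per sub-sample.
#' @param methods Subset of `"face_value"`, `"t_test_right"`,
#'   `"t_test_left"`, `"lognormal"`, `"bayesian_bootstrap"`.
#' @param n_hours Population length when generating from presets.
#' @param quantile_type Shared quantile rule (default type 7).
#' @param prior A [prior_spec()] for the lognormal model.
#' @param alpha Significance level for the t-test methods.
#' @param boundaries A [class_boundaries()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(presets = c("good_near_boundary", "moderate_far"),
                              csv_paths = character(0),
                              schemes = list(scheme_om(), scheme_sm()),
                              reps = 10000L, n_draws = 1000L,
                              methods = c("face_value", "t_test_right",
                                          "t_test_left", "lognormal",
                                          "bayesian_bootstrap"),
                              n_hours = 26280L,
                              quantile_type = q95_default_type,
                              prior = prior_spec(), alpha = 0.01,
                              boundaries = class_boundaries(), seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- as.integer(reps); n_draws <- as.integer(n_draws)
  if (is.na(reps) || reps < 1L) stop_arg("reps must be >= 1")
  if (is.na(n_draws) || n_draws < 100L) stop_arg("n_draws must be >= 100")
  for (p in presets) preset_scenario(p)  # unknown names fail here
  for (f in csv_paths) if (!file.exists(f))
    stop_arg("population CSV not found: %s", f)
  structure(list(presets = presets, csv_paths = csv_paths, schemes = schemes,
                 reps = reps, n_draws = n_draws, methods = methods,
                 n_hours = as.integer(n_hours),
                 quantile_type = quantile_type, prior = prior, alpha = alpha,
                 boundaries = boundaries, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read a population series from CSV
#'
#' Expects the header `timestamp,concentration_mgP_L` with ISO-8601
#' timestamps. Rows with missing or nonpositive concentrations are
#' rejected with a row-numbered message.
#'
#' @param path CSV file path.
#' @return A `population_series`.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "concentration_mgP_L")
  if (!all(need %in% names(df)))
    stop_arg("expected header %s, got %s", paste(need, collapse = ","),
             paste(names(df), collapse = ","))
  if (nrow(df) == 0L) stop_arg("empty data section in %s", path)
  conc <- suppressWarnings(as.numeric(df$concentration_mgP_L))
  bad <- which(is.na(conc) | conc <= 0)
  if (length(bad))
    stop_arg("invalid concentration in row(s) %s of %s (must be positive numbers)",
             paste(utils::head(bad, 10L), collapse = ", "), path)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts))
    stop_arg("unparseable timestamp in row(s) %s of %s",
             paste(utils::head(which(is.na(ts)), 10L), collapse = ", "), path)
  structure(list(timestamps = ts, values = conc), class = "population_series")
}

# Deterministic derived seeds: a small multiplicative hash of the master
# seed and a stage counter, kept below 2^31 so it is a valid integer seed.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + counter * 69621) %% 2147483647)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full benchmarking experiment
#'
#' For every population x scheme combination: simulates the sampling
#' distributions of the mean and 95th percentile (bias, skewness, HDI95
#' width), runs the requested inference methods on each sub-sample, and
#' aggregates (a) second-order uncertainty summaries (hit rate, HDI95
#' width and RMBE quantiles) for the Bayesian methods and (b) status
#' frequencies and misgrading rates against the benchmark status for the
#' classification methods, plus class-probability summaries for the
#' Bayesian methods. Fully reproducible from `(config, seed)`: every stage
#' draws from its own derived seed, so enlarging `reps` does not reshuffle
#' earlier replicates.
#'
#' @param config An [experiment_config()].
#' @param verbose Log per-stage progress and timings to stderr?
#' @return A nested list (`report bundle`), one element per population,
#'   each with `benchmark`, `benchmark_status` and one element per scheme
#'   containing `sampling` (per statistic), `second_order` (per Bayesian
#'   method x statistic), `status_frequencies` and `misgrading` (per
#'   method), and `class_probability_summary` (per Bayesian method).
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  populations <- list()
  ctr <- 0L
  for (p in config$presets) {
    ctr <- ctr + 1L
    populations[[p]] <- generate_population(
      preset_scenario(p)$spec, n_hours = config$n_hours,
      seed = derive_seed(config$seed, ctr))
  }
  for (f in config$csv_paths)
    populations[[basename(f)]] <- read_series_csv(f)

  report <- list()
  for (pop_name in names(populations)) {
    t_pop <- Sys.time()
    series <- populations[[pop_name]]
    bench <- benchmark_statistics(series, type = config$quantile_type)
    bench_status <- combine_status(
      classify_statistic(bench[["mean"]], "mean", config$boundaries),
      classify_statistic(bench[["q95"]], "q95", config$boundaries))
    pop_report <- list(benchmark = bench,
                       benchmark_status = as.character(bench_status))
    for (scheme in config$schemes) {
      t0 <- Sys.time()
      ctr <- ctr + 1L
      sub <- draw_subsample_matrix(series, scheme, config$reps,
                                   seed = derive_seed(config$seed, ctr))
      stats_mat <- rbind(
        mean = colMeans(sub),
        q95 = apply(sub, 2L, quantile_value, p = 0.95,
                    type = config$quantile_type))
      sampling <- list()
      for (which in c("mean", "q95")) {
        sd_ <- sampling_distribution(which, stats_mat[which, ],
                                     bench[[which]])
        sampling[[which]] <- c(summarize_sampling(sd_),
                               benchmark = bench[[which]])
      }
      scheme_report <- list(scheme = scheme$name, n = scheme$n,
                            sampling = sampling)

      statuses <- list()
      if ("face_value" %in% config$methods)
        statuses$face_value <- apply(sub, 2L, function(s)
          as.character(face_value_status(s, config$boundaries,
                                         type = config$quantile_type)))
      if ("t_test_right" %in% config$methods)
        statuses$t_test_right <- apply(sub, 2L, function(s)
          as.character(t_test_status(s, config$boundaries,
                                     alpha = config$alpha, tail = "right")))
      if ("t_test_left" %in% config$methods)
        statuses$t_test_left <- apply(sub, 2L, function(s)
          as.character(t_test_status(s, config$boundaries,
                                     alpha = config$alpha, tail = "left")))

      second_order <- list()
      probs_summary <- list()
      for (method in intersect(config$methods,
                               c("lognormal", "bayesian_bootstrap"))) {
        ctr <- ctr + 1L
        base_seed <- derive_seed(config$seed, ctr)
        intervals <- list(mean = vector("list", config$reps),
                          q95 = vector("list", config$reps))
        rmbes <- list(mean = numeric(config$reps),
                      q95 = numeric(config$reps))
        probs <- matrix(NA_real_, nrow = config$reps, ncol = 3L,
                        dimnames = list(NULL, c("High", "Good", "Moderate")))
        map_status <- character(config$reps)
        for (i in seq_len(config$reps)) {
          s_i <- sub[, i]
          post <- if (method == "lognormal") {
            lognormal_posterior(s_i, n_draws = config$n_draws,
                                prior = config$prior,
                                seed = derive_seed(base_seed, i))
          } else {
            bayesian_bootstrap(s_i, n_draws = config$n_draws,
                               seed = derive_seed(base_seed, i))
          }
          for (which in c("mean", "q95")) {
            d <- post[[paste0("draws_", which)]]
            intervals[[which]][[i]] <- hdi(d, 0.95)
            rmbes[[which]][i] <- rmbe(d, bench[[which]])
          }
          cp <- bayes_class_probabilities(post, config$boundaries)
          probs[i, ] <- as.numeric(cp)
          map_status[i] <- names(cp)[which.max(cp)]
        }
        second_order[[method]] <- lapply(
          stats::setNames(c("mean", "q95"), c("mean", "q95")),
          function(which) summarize_second_order(
            intervals[[which]], rmbes[[which]], bench[[which]],
            type = config$quantile_type))
        probs_summary[[method]] <- apply(probs, 2L, function(col)
          stats::setNames(quantile_value(col, c(0.25, 0.5, 0.75),
                                         type = config$quantile_type),
                          c("q25", "median", "q75")))
        statuses[[method]] <- map_status
      }

      scheme_report$second_order <- second_order
      scheme_report$class_probability_summary <- probs_summary
      scheme_report$status_frequencies <- lapply(statuses, function(st)
        100 * prop.table(table(factor(st,
          levels = c("High", "Good", "Moderate")))))
      scheme_report$misgrading <- lapply(statuses, misgrade_frequency,
                                         benchmark = bench_status)
      pop_report[[scheme$name]] <- scheme_report
      log_stage(verbose, "[%s/%s] done in %.1fs", pop_name, scheme$name,
                as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
    report[[pop_name]] <- pop_report
    log_stage(verbose, "[%s] population complete in %.1fs", pop_name,
              as.numeric(difftime(Sys.time(), t_pop, units = "secs")))
  }
  report
}
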