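#' Configure a coverage experiment
#'
#' Captures everything one batch of the interval-coverage simulation needs:
#' the population being sampled, the interval procedure under test, the
#' per-interval sample size, the confidence level, how many intervals to
#' build per batch, and the root seed. Proportion targets additionally need
#' a [success_region()] defining what counts as a success.
#'
#' @param spec a [dist_spec()]: the population sampled.
#' @param target interval procedure: one of `"mean_known_sigma"`,
#'   `"mean_unknown_sigma"`, `"variance_chisq"`, `"variance_large"`,
#'   `"proportion_wald"`, `"proportion_wilson"`, `"proportion_exact"`,
#'   `"mle_poisson"`, `"mle_exponential"`.
#' @param n sample size per interval.
#' @param level confidence level in (0, 1).
#' @param n_intervals number of intervals per batch (K).
#' @param success_region a [success_region()]; required iff `target` is a
#'   proportion method.
#' @param seed integer root seed; batch b uses substream
#'   `child_seed(seed, b)`, so extending a meta-experiment never changes
#'   earlier batches.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(spec,
                              target = c("mean_known_sigma",
                                         "mean_unknown_sigma",
                                         "variance_chisq", "variance_large",
                                         "proportion_wald",
                                         "proportion_wilson",
                                         "proportion_exact",
                                         "mle_poisson", "mle_exponential"),
                              n, level = 0.95, n_intervals = 50L,
                              success_region = NULL, seed = 1L) {
  assert_dist_spec(spec)
  target <- match.arg(target)
  check_level(level)
  for (v in list(n = n, n_intervals = n_intervals)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop("`n` and `n_intervals` must be positive integers", call. = FALSE)
  }
  is_prop <- startsWith(target, "proportion_")
  if (is_prop && is.null(success_region))
    stop("proportion targets require a `success_region`", call. = FALSE)
  if (!is_prop && !is.null(success_region))
    stop("`success_region` only applies to proportion targets",
         call. = FALSE)
  if (!is.null(success_region) &&
      !inherits(success_region, "success_region"))
    stop("`success_region` must be a success_region object", call. = FALSE)
  if (target == "mle_poisson" &&
      !spec$family %in% c("poisson", "bernoulli"))
    stop("mle_poisson requires a count-valued family", call. = FALSE)
  if (target == "mle_exponential" && spec$family != "exponential")
    stop("mle_exponential requires the exponential family", call. = FALSE)
  if (target == "mean_unknown_sigma" && n < 2)
    stop("mean_unknown_sigma requires n >= 2", call. = FALSE)
  if (startsWith(target, "variance_") && n < 2)
    stop("variance targets require n >= 2", call. = FALSE)
  structure(list(spec = spec, target = target, n = as.integer(n),
                 level = level, n_intervals = as.integer(n_intervals),
                 success_region = success_region, seed = as.integer(seed)),
            class = "experiment_config")
}

# true value of the target parameter for a config
true_value_of <- function(config) {
  truth <- population_summary(config$spec)
  switch(config$target,
    mean_known_sigma = ,
    mean_unknown_sigma = truth$mean,
    variance_chisq = ,
    variance_large = truth$variance,
    proportion_wald = ,
    proportion_wilson = ,
    proportion_exact = success_probability(config$spec,
                                           config$success_region),
    mle_poisson = config$spec$params$lambda,
    mle_exponential = config$spec$params$rate)
}

# apply the configured estimator to one sample
estimate_interval <- function(config, values) {
  switch(config$target,
    mean_known_sigma = mean_ci_z(
      values, sigma = sqrt(population_summary(config$spec)$variance),
      level = config$level),
    mean_unknown_sigma = mean_ci_t(values, level = config$level),
    variance_chisq = variance_ci_chisquare(values, level = config$level),
    variance_large = variance_ci_large_sample(values, level = config$level),
    proportion_wald = ,
    proportion_wilson = ,
    proportion_exact = {
      r <- config$success_region
      x <- sum(values >= r$left & values <= r$right)
      fn <- switch(config$target,
                   proportion_wald = proportion_ci_wald,
                   proportion_wilson = proportion_ci_wilson,
                   proportion_exact = proportion_ci_exact)
      fn(x, length(values), level = config$level)
    },
    mle_poisson = suppressWarnings(
      poisson_lambda_ci(values, level = config$level))$interval,
    mle_exponential = exponential_rate_ci(values,
                                          level = config$level)$interval)
}

#' Run one batch of the coverage experiment
#'
#' Draws `n_intervals` independent samples of size `n` from the configured
#' population, applies the configured interval procedure to each, and
#' counts how many intervals miss the true parameter value. A miss is
#' strict: the truth lies strictly outside \eqn{[lower, upper]}; boundary
#' contact counts as covered.
#'
#' @param config an [experiment_config()].
#' @param batch_index substream index (default 1); [run_meta()] passes the
#'   batch number here so batches are independent and reproducible.
#' @return an object of class `batch_result`: a data frame of intervals
#'   (`lower`, `upper`, `point`, `covered`) plus `true_value` and
#'   `n_missed`.
#' @export
run_batch <- function(config, batch_index = 1L) {
  if (!inherits(config, "experiment_config"))
    stop("`config` must be an experiment_config", call. = FALSE)
  truth <- true_value_of(config)
  K <- config$n_intervals
  batch_seed <- child_seed(config$seed, batch_index)
  ints <- with_seed(batch_seed, {
    lapply(seq_len(K), function(k)
      estimate_interval(config, draw_sample(config$spec, config$n)))
  })
  lower <- vapply(ints, `[[`, numeric(1), "lower")
  upper <- vapply(ints, `[[`, numeric(1), "upper")
  point <- vapply(ints, `[[`, numeric(1), "point")
  covered <- truth >= lower & truth <= upper
  structure(list(
    intervals = data.frame(lower = lower, upper = upper, point = point,
                           covered = covered),
    true_value = truth,
    covered = covered,
    n_missed = sum(!covered),
    batch_index = as.integer(batch_index)
  ), class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  K <- nrow(x$intervals)
  cat(sprintf("<batch_result> %d intervals, true value %.6g, %d missed (coverage %.3f)\n",
              K, x$true_value, x$n_missed, 1 - x$n_missed / K))
  invisible(x)
}

#' Repeat a coverage experiment as a meta-experiment
#'
#' Runs `n_runs` independent batches (substreams derived from the root seed
#' and the batch index) and aggregates the per-batch miss counts into the
#' average number of misses and the average empirical coverage.
#'
#' @param config an [experiment_config()].
#' @param n_runs number of batches (>= 1).
#' @return an object of class `meta_result`: `runs` (data frame with
#'   `batch`, `n_missed`), `mean_missed`, `mean_coverage`, and the config.
#' @examples
#' cfg <- experiment_config(dist_spec("normal", mu = 5, sigma = 2),
#'                          "mean_known_sigma", n = 30, n_intervals = 20)
#' run_meta(cfg, n_runs = 10)
#' @export
run_meta <- function(config, n_runs) {
  if (!inherits(config, "experiment_config"))
    stop("`config` must be an experiment_config", call. = FALSE)
  if (!is.numeric(n_runs) || length(n_runs) != 1L || is.na(n_runs) ||
      n_runs < 1 || n_runs != round(n_runs))
    stop("`n_runs` must be a positive integer", call. = FALSE)
  batches <- lapply(seq_len(n_runs), function(b) run_batch(config, b))
  missed <- vapply(batches, `[[`, numeric(1), "n_missed")
  structure(list(
    runs = data.frame(batch = seq_len(n_runs), n_missed = missed),
    batches = batches,
    mean_missed = mean(missed),
    mean_coverage = 1 - mean(missed) / config$n_intervals,
    config = config
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %d runs x %d intervals (%s): mean missed %.3f, mean coverage %.4f\n",
    nrow(x$runs), x$config$n_intervals, x$config$target, x$mean_missed,
    x$mean_coverage))
  invisible(x)
}

#' Exact coverage of a binomial proportion interval by enumeration
#'
#' Computes \eqn{\sum_{x=0}^n \binom{n}{x} p^x (1-p)^{n-x}\,
#' 1\{\mathrm{interval}(x, n) \ni p\}} — the exact coverage probability of
#' the Wald, Wilson or Clopper-Pearson interval at a given true p, with no
#' simulation. This is the deterministic oracle the Monte Carlo engine is
#' checked against, and it reproduces the Wald interval's coverage collapse
#' near the parameter boundary exactly.
#'
#' @param n number of trials.
#' @param p true success probability.
#' @param level confidence level in (0, 1).
#' @param method `"wald"`, `"wilson"` or `"exact"`.
#' @return the exact coverage probability.
#' @examples
#' exact_binomial_coverage(20, 0.95, method = "wald")   # far below 0.95
#' exact_binomial_coverage(20, 0.95, method = "exact")  # >= 0.95
#' @export
exact_binomial_coverage <- function(n, p, level = 0.95,
                                    method = c("wald", "wilson", "exact")) {
  method <- match.arg(method)
  check_level(level)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a probability", call. = FALSE)
  fn <- switch(method, wald = proportion_ci_wald,
               wilson = proportion_ci_wilson, exact = proportion_ci_exact)
  xs <- 0:n
  covers <- vapply(xs, function(x) {
    ci <- fn(x, n, level = level)
    p >= ci$lower && p <= ci$upper
  }, logical(1))
  sum(stats::dbinom(xs, n, p)[covers])
}
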