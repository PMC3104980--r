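#' Percentile-bootstrap confidence interval for an arbitrary statistic
#'
#' Draws `n_resamples` with-replacement resamples of the original size,
#' evaluates `statistic` on each, and takes the empirical \eqn{\alpha/2} and
#' \eqn{1-\alpha/2} quantiles (type-7 linear interpolation) of the resampled
#' statistics as interval bounds.
#'
#' @param values numeric data vector, length >= 2.
#' @param statistic function mapping a numeric vector to a single number.
#' @param n_resamples number of bootstrap resamples (>= 100).
#' @param level confidence level in (0, 1).
#' @param seed integer seed; identical inputs and seed reproduce the
#'   interval exactly.
#' @return an object of class `bootstrap_result`: `point` (statistic on the
#'   original data), `lower`, `upper`, `level`, `n_resamples`, `seed`, and
#'   `stat_range` (min/max of the resampled statistics).
#' @examples
#' bootstrap_percentile_ci(rexp(50), stats::median, n_resamples = 1000,
#'                         level = 0.99, seed = 1)
#' @export
bootstrap_percentile_ci <- function(values, statistic, n_resamples = 20000L,
                                    level = 0.95, seed = 1L) {
  check_level(level)
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    stop("`values` must be a numeric vector of length >= 2 without NAs",
         call. = FALSE)
  if (!is.function(statistic)) stop("`statistic` must be a function",
                                    call. = FALSE)
  if (!is.numeric(n_resamples) || length(n_resamples) != 1L ||
      is.na(n_resamples) || n_resamples < 100 ||
      n_resamples != round(n_resamples))
    stop("`n_resamples` must be an integer >= 100", call. = FALSE)
  n <- length(values)
  B <- as.integer(n_resamples)
  stats_boot <- with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    resamples <- matrix(values[idx], nrow = n, ncol = B)
    apply(resamples, 2L, statistic)
  })
  if (!is.numeric(stats_boot) || anyNA(stats_boot))
    stop("`statistic` must return a single finite number per resample",
         call. = FALSE)
  a <- (1 - level) / 2
  q <- stats::quantile(stats_boot, probs = c(a, 1 - a), names = FALSE,
                       type = 7)
  structure(list(
    point = statistic(values),
    lower = q[1], upper = q[2],
    level = level, n_resamples = B, seed = seed,
    stat_range = range(stats_boot)
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> point = %.6g, %g%% percentile CI [%.6g, %.6g] (B = %d)\n",
    x$point, 100 * x$level, x$lower, x$upper, x$n_resamples))
  invisible(x)
}

#' Bootstrap median point and interval estimate
#'
#' Convenience wrapper for the protocol used for surface-complexity
#' summaries: point estimate the sample median, percentile bootstrap with
#' 20,000 resamples, default level 0.99.
#'
#' @param values numeric data vector, length >= 2.
#' @param level confidence level (default 0.99).
#' @param seed integer seed.
#' @return a `bootstrap_result`.
#' @export
median_point_and_ci <- function(values, level = 0.99, seed = 1L) {
  bootstrap_percentile_ci(values, stats::median, n_resamples = 20000L,
                          level = level, seed = seed)
}
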