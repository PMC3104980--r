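#' Sufficient statistics of one sample
#'
#' Computes the summary a confidence-interval estimator needs: sample size,
#' mean, standard deviation (divisor \eqn{n-1}), and the plug-in central
#' moments \eqn{m_2} and \eqn{m_4} (divisor \eqn{n}), the latter feeding the
#' large-sample variance interval.
#'
#' @param values numeric vector, length >= 1.
#' @return an object of class `sample_moments` with fields `n`, `mean`,
#'   `sd`, `m2`, `m4`.
#' @examples
#' sample_moments(c(1, 2, 3, 4, 5))
#' @export
sample_moments <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values))
    stop("`values` must be a non-empty numeric vector without NAs",
         call. = FALSE)
  n <- length(values)
  m <- mean(values)
  d <- values - m
  structure(list(
    n = n,
    mean = m,
    sd = if (n > 1) stats::sd(values) else 0,
    m2 = mean(d^2),
    m4 = mean(d^4)
  ), class = "sample_moments")
}

#' @export
print.sample_moments <- function(x, ...) {
  cat(sprintf("<sample_moments> n = %d, mean = %g, sd = %g, m2 = %g, m4 = %g\n",
              x$n, x$mean, x$sd, x$m2, x$m4))
  invisible(x)
}

as_sample_moments <- function(x) {
  if (inherits(x, "sample_moments")) x else sample_moments(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop("`level` must be a probability strictly between 0 and 1",
         call. = FALSE)
  level
}

z_crit <- function(level) stats::qnorm(1 - (1 - level) / 2)

interval_estimate <- function(lower, upper, level, method, point) {
  # guard against floating-point inversion in degenerate cases
  if (lower > upper && lower - upper < 1e-12) lower <- upper
  stopifnot(lower <= upper)
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, point = point),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%g%% %s interval: [%.6g, %.6g]  (point = %.6g)\n",
              100 * x$level, x$method, x$lower, x$upper, x$point))
  invisible(x)
}

#' z-interval for a mean with known population standard deviation
#'
#' \eqn{\bar x \pm z_{\alpha/2}\,\sigma/\sqrt n}. Because \eqn{\sigma} is
#' assumed known, every sample of the same size yields an interval of
#' identical width \eqn{2 z_{\alpha/2} \sigma / \sqrt n}.
#'
#' @param m a [sample_moments()] object or a numeric vector of observations.
#' @param sigma known population standard deviation (> 0).
#' @param level confidence level in (0, 1).
#' @return an `interval_estimate`.
#' @export
mean_ci_z <- function(m, sigma, level = 0.95) {
  m <- as_sample_moments(m)
  check_level(level)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  hw <- z_crit(level) * sigma / sqrt(m$n)
  interval_estimate(m$mean - hw, m$mean + hw, level, "mean_z", m$mean)
}

#' t-interval for a mean with unknown population standard deviation
#'
#' \eqn{\bar x \pm t_{\alpha/2, n-1}\, s/\sqrt n}. Generally wider than the
#' z-interval at the same level, and its width varies from sample to sample
#' because the sample standard deviation is used.
#'
#' @inheritParams mean_ci_z
#' @return an `interval_estimate`.
#' @export
mean_ci_t <- function(m, level = 0.95) {
  m <- as_sample_moments(m)
  check_level(level)
  if (m$n < 2) stop("t-interval requires n >= 2", call. = FALSE)
  hw <- stats::qt(1 - (1 - level) / 2, df = m$n - 1) * m$sd / sqrt(m$n)
  interval_estimate(m$mean - hw, m$mean + hw, level, "mean_t", m$mean)
}

#' Chi-square interval for a population variance
#'
#' \eqn{[(n-1)s^2/\chi^2_{1-\alpha/2,n-1},\ (n-1)s^2/\chi^2_{\alpha/2,n-1}]},
#' where \eqn{\chi^2_{q,\nu}} denotes the lower-tail q-quantile. Exact under
#' normal sampling; its coverage degrades badly for heavy-tailed populations
#' (e.g. exponential) and does not improve with sample size, because the
#' sampling variance of \eqn{s^2} depends on the population kurtosis.
#'
#' @inheritParams mean_ci_z
#' @return an `interval_estimate` with point estimate \eqn{s^2}.
#' @export
variance_ci_chisquare <- function(m, level = 0.95) {
  m <- as_sample_moments(m)
  check_level(level)
  if (m$n < 2) stop("variance interval requires n >= 2", call. = FALSE)
  a <- (1 - level) / 2
  ss <- (m$n - 1) * m$sd^2
  if (ss == 0) return(interval_estimate(0, 0, level, "var_chisq", 0))
  interval_estimate(ss / stats::qchisq(1 - a, df = m$n - 1),
                    ss / stats::qchisq(a, df = m$n - 1),
                    level, "var_chisq", m$sd^2)
}

#' Large-sample distribution-free interval for a population variance
#'
#' Based on the asymptotic normality of \eqn{s^2} with variance
#' \eqn{(\mu_4 - \sigma^4)/n}: the interval is
#' \eqn{s^2 \pm z_{\alpha/2}\sqrt{(m_4 - m_2^2)/n}}, with the unknown fourth
#' central moment \eqn{\mu_4} replaced by the fourth sample moment
#' \eqn{m_4}. The lower bound is truncated at 0. Unlike the chi-square
#' interval this makes no normality assumption and restores near-nominal
#' coverage for non-normal populations at large n.
#'
#' @inheritParams mean_ci_z
#' @return an `interval_estimate` with point estimate \eqn{s^2}.
#' @export
variance_ci_large_sample <- function(m, level = 0.95) {
  m <- as_sample_moments(m)
  check_level(level)
  if (m$n < 2) stop("variance interval requires n >= 2", call. = FALSE)
  hw <- z_crit(level) * sqrt(max(0, m$m4 - m$m2^2) / m$n)
  s2 <- m$sd^2
  interval_estimate(max(0, s2 - hw), s2 + hw, level, "var_large", s2)
}

check_counts <- function(x, n) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop("`x` must be a nonnegative integer count", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (x > n) stop("`x` cannot exceed `n`", call. = FALSE)
  invisible(TRUE)
}

#' Wald interval for a proportion
#'
#' \eqn{\hat p \pm z_{\alpha/2}\sqrt{\hat p(1-\hat p)/n}}, clipped to
#' \eqn{[0,1]}. Simple but known to under-cover when n is small or
#' \eqn{\hat p} is near 0 or 1; at \eqn{x = 0} or \eqn{x = n} it degenerates
#' to a zero-width interval (returned as such, not an error — the
#' degeneracy is the phenomenon the coverage simulations demonstrate).
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level in (0, 1).
#' @return an `interval_estimate`.
#' @export
proportion_ci_wald <- function(x, n, level = 0.95) {
  check_counts(x, n); check_level(level)
  phat <- x / n
  hw <- z_crit(level) * sqrt(phat * (1 - phat) / n)
  interval_estimate(max(0, phat - hw), min(1, phat + hw), level,
                    "prop_wald", phat)
}

#' Wilson score interval for a proportion
#'
#' Inverts the score test: center \eqn{(\hat p + z^2/2n)/(1 + z^2/n)},
#' half-width \eqn{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1 + z^2/n)}.
#' Better small-sample coverage than Wald without being conservative like
#' the exact interval; never degenerates to zero width.
#'
#' @inheritParams proportion_ci_wald
#' @return an `interval_estimate` (point estimate is \eqn{\hat p}).
#' @export
proportion_ci_wilson <- function(x, n, level = 0.95) {
  check_counts(x, n); check_level(level)
  phat <- x / n
  z <- z_crit(level)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  interval_estimate(max(0, center - hw), min(1, center + hw), level,
                    "prop_wilson", phat)
}

#' Exact (Clopper-Pearson) interval for a proportion
#'
#' Inverts the binomial tails; computed through F-distribution quantiles:
#' \deqn{lower = \frac{x}{x + (n-x+1) F_{1-\alpha/2;\, 2(n-x+1),\, 2x}},\quad
#'       upper = \frac{(x+1) F_{1-\alpha/2;\, 2(x+1),\, 2(n-x)}}
#'                    {n-x + (x+1) F_{1-\alpha/2;\, 2(x+1),\, 2(n-x)}}}
#' with the conventions \eqn{lower = 0} at \eqn{x = 0} and \eqn{upper = 1} at
#' \eqn{x = n}. Coverage is guaranteed to be at least the nominal level for
#' every true p, at the price of conservatism.
#'
#' @inheritParams proportion_ci_wald
#' @return an `interval_estimate`.
#' @export
proportion_ci_exact <- function(x, n, level = 0.95) {
  check_counts(x, n); check_level(level)
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else {
    f <- stats::qf(1 - a, df1 = 2 * (n - x + 1), df2 = 2 * x)
    x / (x + (n - x + 1) * f)
  }
  upper <- if (x == n) 1 else {
    f <- stats::qf(1 - a, df1 = 2 * (x + 1), df2 = 2 * (n - x))
    (x + 1) * f / (n - x + (x + 1) * f)
  }
  interval_estimate(lower, upper, level, "prop_exact", x / n)
}
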