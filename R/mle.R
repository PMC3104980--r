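#' Asymptotic confidence interval from the Fisher information
#'
#' For large n the maximum-likelihood estimate \eqn{\hat\theta} is
#' approximately normal with mean \eqn{\theta} and variance equal to the
#' Cramer-Rao lower bound \eqn{1/(n I_1(\theta))}, where \eqn{I_1} is the
#' per-observation Fisher information. Evaluating the information at the
#' plug-in \eqn{\hat\theta} gives the interval
#' \eqn{\hat\theta \pm z_{\alpha/2} / \sqrt{n I_1(\hat\theta)}}.
#'
#' @param theta_hat maximum-likelihood point estimate.
#' @param unit_information per-observation Fisher information evaluated at
#'   `theta_hat`; must be positive.
#' @param n sample size.
#' @param level confidence level in (0, 1).
#' @param method tag recorded on the interval (default `"fisher"`).
#' @return an object of class `mle_interval`: list with `theta_hat`,
#'   `unit_information`, `n` and `interval` (an `interval_estimate`).
#' @examples
#' fisher_ci(5, unit_information = 0.04, n = 25)  # SE = 1
#' @export
fisher_ci <- function(theta_hat, unit_information, n, level = 0.95,
                      method = "fisher") {
  check_level(level)
  if (!is.numeric(unit_information) || length(unit_information) != 1L ||
      is.na(unit_information) || unit_information <= 0)
    stop("`unit_information` must be positive", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  hw <- z_crit(level) / sqrt(n * unit_information)
  structure(list(
    theta_hat = theta_hat,
    unit_information = unit_information,
    n = as.integer(n),
    interval = interval_estimate(theta_hat - hw, theta_hat + hw, level,
                                 method, theta_hat)
  ), class = "mle_interval")
}

#' @export
print.mle_interval <- function(x, ...) {
  cat(sprintf("<mle_interval> theta_hat = %.6g, n = %d, I1 = %.6g\n",
              x$theta_hat, x$n, x$unit_information))
  print(x$interval)
  invisible(x)
}

#' Asymptotic MLE interval for a Poisson rate
#'
#' The MLE of \eqn{\lambda} is \eqn{\bar x} and the per-observation Fisher
#' information is \eqn{I_1(\lambda) = 1/\lambda}, giving
#' \eqn{\bar x \pm z_{\alpha/2}\sqrt{\bar x / n}}.
#'
#' An all-zero sample has \eqn{\hat\lambda = 0} and an information estimate
#' of 0; a degenerate \eqn{[0, 0]} interval is returned with a warning
#' rather than an error so that simulation runs survive rare degenerate
#' draws.
#'
#' @param values nonnegative integer counts.
#' @param level confidence level in (0, 1).
#' @return an `mle_interval`.
#' @examples
#' poisson_lambda_ci(pine_tree_data())
#' @export
poisson_lambda_ci <- function(values, level = 0.95) {
  check_level(level)
  if (!is.numeric(values) || length(values) < 1L || anyNA(values) ||
      any(values < 0) || any(values != round(values)))
    stop("`values` must be nonnegative integer counts", call. = FALSE)
  n <- length(values)
  xbar <- mean(values)
  if (xbar == 0) {
    warning("all-zero sample: Fisher information estimate is 0; ",
            "returning degenerate [0, 0] interval")
    return(structure(list(
      theta_hat = 0, unit_information = Inf, n = n,
      interval = interval_estimate(0, 0, level, "mle_poisson", 0)
    ), class = "mle_interval"))
  }
  fisher_ci(xbar, unit_information = 1 / xbar, n = n, level = level,
            method = "mle_poisson")
}

#' Asymptotic MLE interval for an exponential rate
#'
#' The MLE of the rate is \eqn{\hat\lambda = 1/\bar x} with
#' \eqn{I_1(\lambda) = 1/\lambda^2}, giving
#' \eqn{\hat\lambda \pm z_{\alpha/2}\, \hat\lambda/\sqrt n}.
#'
#' @param values strictly positive observations.
#' @param level confidence level in (0, 1).
#' @return an `mle_interval`.
#' @export
exponential_rate_ci <- function(values, level = 0.95) {
  check_level(level)
  if (!is.numeric(values) || length(values) < 1L || anyNA(values) ||
      any(values <= 0))
    stop("`values` must be strictly positive", call. = FALSE)
  rate_hat <- 1 / mean(values)
  fisher_ci(rate_hat, unit_information = 1 / rate_hat^2, n = length(values),
            level = level, method = "mle_exponential")
}
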