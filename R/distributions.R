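#' Specify a parametric sampling distribution
#'
#' A `dist_spec` records the population a coverage experiment samples from:
#' one of six parametric families plus its parameters. Parameters are
#' validated at construction; downstream code can therefore assume a valid
#' spec.
#'
#' Supported families and parameters:
#' \describe{
#'   \item{`normal`}{`mu` (mean), `sigma` (> 0, standard deviation).}
#'   \item{`exponential`}{`rate` (> 0); mean is `1/rate`.}
#'   \item{`poisson`}{`lambda` (> 0).}
#'   \item{`bernoulli`}{`p` in \eqn{[0, 1]}.}
#'   \item{`uniform`}{`a`, `b` with `a < b`.}
#'   \item{`generalized_beta`}{`alpha`, `beta` (> 0, shape) and location
#'     limits `left < right`: a standard Beta on \eqn{[0,1]} mapped affinely
#'     onto \eqn{[left, right]}.}
#' }
#'
#' @param family one of `"normal"`, `"exponential"`, `"poisson"`,
#'   `"bernoulli"`, `"uniform"`, `"generalized_beta"`.
#' @param ... named numeric parameters for the family (see Details).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("normal", mu = 5, sigma = 2)
#' dist_spec("generalized_beta", alpha = 1.59, beta = 3.15, left = 3.4, right = 10.8)
#' @export
dist_spec <- function(family = c("normal", "exponential", "poisson",
                                 "bernoulli", "uniform", "generalized_beta"),
                      ...) {
  family <- match.arg(family)
  params <- list(...)
  expected <- switch(family,
    normal = c("mu", "sigma"),
    exponential = "rate",
    poisson = "lambda",
    bernoulli = "p",
    uniform = c("a", "b"),
    generalized_beta = c("alpha", "beta", "left", "right"))
  if (!setequal(names(params), expected)) {
    stop(sprintf("family '%s' requires parameters: %s (got: %s)",
                 family, paste(expected, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- params[expected]
  for (nm in expected) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm),
           call. = FALSE)
  }
  ok <- switch(family,
    normal = params$sigma > 0,
    exponential = params$rate > 0,
    poisson = params$lambda > 0,
    bernoulli = params$p >= 0 && params$p <= 1,
    uniform = params$a < params$b,
    generalized_beta = params$alpha > 0 && params$beta > 0 &&
      params$left < params$right)
  if (!ok) stop(sprintf("invalid parameters for family '%s'", family),
                call. = FALSE)
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

assert_dist_spec <- function(spec) {
  if (!is_dist_spec(spec)) stop("`spec` must be a dist_spec object", call. = FALSE)
  invisible(spec)
}

#' Draw a seeded i.i.d. sample from a distribution spec
#'
#' Identical `(spec, n, seed)` triples give bit-identical samples; the
#' caller's RNG state is left untouched when a seed is supplied.
#'
#' @param spec a [dist_spec()].
#' @param n sample size (positive integer).
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @return a numeric vector of length `n`.
#' @examples
#' draw_sample(dist_spec("normal", mu = 5, sigma = 2), 30, seed = 7)
#' @export
draw_sample <- function(spec, n, seed = NULL) {
  assert_dist_spec(spec)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 ||
      n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  p <- spec$params
  with_seed(seed, switch(spec$family,
    normal = stats::rnorm(n, p$mu, p$sigma),
    exponential = stats::rexp(n, p$rate),
    poisson = stats::rpois(n, p$lambda),
    bernoulli = stats::rbinom(n, 1L, p$p),
    uniform = stats::runif(n, p$a, p$b),
    generalized_beta = p$left + (p$right - p$left) *
      stats::rbeta(n, p$alpha, p$beta)))
}

# raw moments E X^k of the standard Beta(alpha, beta), k = 1..4
beta_raw_moments <- function(alpha, beta) {
  s <- alpha + beta
  m <- numeric(4)
  m[1] <- alpha / s
  for (k in 2:4) m[k] <- m[k - 1] * (alpha + k - 1) / (s + k - 1)
  m
}

#' Exact population moments of a distribution spec
#'
#' Returns the closed-form mean, variance and fourth central moment
#' \eqn{\mu_4 = E[(X-\mu)^4]} of the family — the ground truth the coverage
#' engine checks intervals against. \eqn{\mu_4} drives the sampling variance
#' of \eqn{s^2} under non-normality (asymptotic variance \eqn{\mu_4 -
#' \sigma^4}), which is why the chi-square variance interval fails for
#' heavy-tailed populations.
#'
#' @param spec a [dist_spec()].
#' @return an object of class `population_truth`: a list with `mean`,
#'   `variance` and `fourth_central_moment`.
#' @examples
#' population_summary(dist_spec("normal", mu = 5, sigma = 2))   # mu4 = 3 sigma^4
#' population_summary(dist_spec("exponential", rate = 5))       # mu4 = 9 / rate^4
#' @export
population_summary <- function(spec) {
  assert_dist_spec(spec)
  p <- spec$params
  out <- switch(spec$family,
    normal = list(mean = p$mu, variance = p$sigma^2,
                  fourth_central_moment = 3 * p$sigma^4),
    exponential = list(mean = 1 / p$rate, variance = 1 / p$rate^2,
                       fourth_central_moment = 9 / p$rate^4),
    poisson = list(mean = p$lambda, variance = p$lambda,
                   fourth_central_moment = p$lambda * (1 + 3 * p$lambda)),
    bernoulli = {
      q <- 1 - p$p
      list(mean = p$p, variance = p$p * q,
           fourth_central_moment = p$p * q * (p$p^3 + q^3))
    },
    uniform = {
      w <- p$b - p$a
      list(mean = (p$a + p$b) / 2, variance = w^2 / 12,
           fourth_central_moment = w^4 / 80)
    },
    generalized_beta = {
      m <- beta_raw_moments(p$alpha, p$beta)
      mu2 <- m[2] - m[1]^2
      mu4 <- m[4] - 4 * m[1] * m[3] + 6 * m[1]^2 * m[2] - 3 * m[1]^4
      w <- p$right - p$left
      list(mean = p$left + w * m[1], variance = w^2 * mu2,
           fourth_central_moment = w^4 * mu4)
    })
  structure(out, class = "population_truth")
}

#' @export
print.population_truth <- function(x, ...) {
  cat(sprintf("<population_truth> mean = %g, variance = %g, mu4 = %g\n",
              x$mean, x$variance, x$fourth_central_moment))
  invisible(x)
}

#' Cumulative distribution function of a spec
#'
#' @param spec a [dist_spec()].
#' @param x numeric vector of evaluation points.
#' @return \eqn{F(x) = P(X \le x)}, vectorised over `x`.
#' @examples
#' cdf(dist_spec("exponential", rate = 5), 0.2)  # 1 - exp(-1)
#' @export
cdf <- function(spec, x) {
  assert_dist_spec(spec)
  p <- spec$params
  switch(spec$family,
    normal = stats::pnorm(x, p$mu, p$sigma),
    exponential = stats::pexp(x, p$rate),
    poisson = stats::ppois(floor(x), p$lambda),
    bernoulli = stats::pbinom(floor(x), 1L, p$p),
    uniform = stats::punif(x, p$a, p$b),
    generalized_beta = stats::pbeta((x - p$left) / (p$right - p$left),
                                    p$alpha, p$beta))
}

#' Define a success region
#'
#' A closed interval \eqn{[left, right]}; an observation counts as a
#' "success" when it falls inside, so the region defines a population
#' proportion \eqn{p = P(left \le X \le right)}. For discrete families both
#' endpoints are included.
#'
#' @param left,right region bounds, `left <= right`.
#' @return an object of class `success_region`.
#' @export
success_region <- function(left, right) {
  stopifnot(is.numeric(left), length(left) == 1L,
            is.numeric(right), length(right) == 1L)
  if (is.na(left) || is.na(right) || left > right)
    stop("success region requires left <= right", call. = FALSE)
  structure(list(left = left, right = right), class = "success_region")
}

#' Probability of a success region
#'
#' Computes \eqn{P(left \le X \le right) = F(right) - F(left^-)}. The left
#' endpoint is inclusive, which only matters for the discrete families
#' (Poisson, Bernoulli).
#'
#' @param spec a [dist_spec()].
#' @param region a [success_region()].
#' @return a probability in \eqn{[0, 1]}.
#' @examples
#' success_probability(dist_spec("normal", mu = 5, sigma = 2), success_region(4, 7))
#' @export
success_probability <- function(spec, region) {
  assert_dist_spec(spec)
  if (!inherits(region, "success_region"))
    stop("`region` must be a success_region object", call. = FALSE)
  upper <- cdf(spec, region$right)
  lower <- if (spec$family %in% c("poisson", "bernoulli")) {
    # F(left-) for an integer lattice: mass strictly below ceiling(left)
    k <- ceiling(region$left) - 1
    if (k < 0) 0 else cdf(spec, k)
  } else {
    cdf(spec, region$left)
  }
  max(0, min(1, upper - lower))
}
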