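#' Curvedness of a surface point
#'
#' Given the two principal curvatures \eqn{k_1, k_2} at a point of a
#' surface, the curvedness is \eqn{CV = \sqrt{(k_1^2 + k_2^2)/2}}: a
#' norm-like local measure of how bent the surface is, zero only at a flat
#' point, symmetric in the two curvatures and invariant to their sign.
#'
#' @param k1,k2 principal curvatures (numeric, vectorised).
#' @return nonnegative curvedness values.
#' @examples
#' curvedness(3, 4)  # sqrt(25 / 2)
#' @export
curvedness <- function(k1, k2) {
  if (length(k1) != length(k2))
    stop("`k1` and `k2` must have equal length", call. = FALSE)
  sqrt((k1^2 + k2^2) / 2)
}

#' Global curvedness of a surface
#'
#' The arithmetic mean of the per-vertex curvedness over a whole surface —
#' a single global index of shape complexity. Inputs violating the
#' \eqn{k_1 \ge k_2} convention are accepted (curvedness is symmetric).
#'
#' @param k1,k2 numeric vectors of per-vertex principal curvatures, equal
#'   positive length.
#' @return the mean curvedness.
#' @examples
#' global_curvedness(c(0, 3), c(0, 4))
#' @export
global_curvedness <- function(k1, k2) {
  if (length(k1) < 1L)
    stop("curvature field must contain at least one vertex", call. = FALSE)
  mean(curvedness(k1, k2))
}

#' Fit a generalized (four-parameter) Beta distribution
#'
#' Maximum-likelihood fit of the two shape parameters of a Beta
#' distribution supported on a user-supplied interval \eqn{[left, right]}.
#' The location limits are fixed by the user, not estimated: joint MLE of
#' all four parameters is ill-posed when observations approach the support
#' boundary. Data are affinely rescaled to \eqn{(0, 1)}; values exactly on
#' a boundary are pulled inside by `boundary_shrink` times the support
#' width if that is positive, otherwise they are an error.
#'
#' Optimisation is BFGS on \eqn{(\log\alpha, \log\beta)} with analytic
#' gradients, started from method-of-moments estimates.
#'
#' @param values numeric data, length >= 10, inside `[left, right]`.
#' @param left,right support limits, `left < right`.
#' @param boundary_shrink fraction of the support width by which values
#'   equal to `left` or `right` are moved inward (default 0: boundary
#'   values are rejected).
#' @return an object of class `beta_fit`: `alpha`, `beta`, `left`,
#'   `right`, `loglik`, `converged`.
#' @examples
#' spec <- dist_spec("generalized_beta", alpha = 2, beta = 3,
#'                   left = 0, right = 10)
#' fit_generalized_beta(draw_sample(spec, 500, seed = 1), 0, 10)
#' @export
fit_generalized_beta <- function(values, left, right, boundary_shrink = 0) {
  if (!is.numeric(values) || length(values) < 10L || anyNA(values))
    stop("`values` must be numeric with length >= 10", call. = FALSE)
  if (!(is.numeric(left) && is.numeric(right) && left < right))
    stop("need `left` < `right`", call. = FALSE)
  if (any(values < left | values > right))
    stop("all values must lie within [left, right]", call. = FALSE)
  w <- right - left
  if (boundary_shrink > 0) {
    eps <- boundary_shrink * w
    values[values == left] <- left + eps
    values[values == right] <- right - eps
  }
  if (any(values == left | values == right))
    stop("values on the support boundary; supply `boundary_shrink` > 0",
         call. = FALSE)
  u <- (values - left) / w
  # method-of-moments start
  m <- mean(u); v <- stats::var(u)
  v <- min(v, m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * common, (1 - m) * common), 1e-3))
  n <- length(u)
  slog <- sum(log(u)); slog1 <- sum(log1p(-u))
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -( (a - 1) * slog + (b - 1) * slog1 - n * lbeta(a, b) )
  }
  grad <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    dig <- digamma(a + b)
    ga <- -(slog - n * (digamma(a) - dig)) * a
    gb <- -(slog1 - n * (digamma(b) - dig)) * b
    c(ga, gb)
  }
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
  structure(list(alpha = alpha, beta = beta, left = left, right = right,
                 # log-likelihood on the original scale includes the
                 # Jacobian of the affine rescaling
                 loglik = -opt$value - n * log(w),
                 converged = opt$convergence == 0L),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf(
    "<beta_fit> alpha = %.4f, beta = %.4f on [%g, %g], logLik = %.2f%s\n",
    x$alpha, x$beta, x$left, x$right, x$loglik,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Kolmogorov-Smirnov distance between data and a model
#'
#' The supremum distance \eqn{D = \sup_x |F_n(x) - F(x)|} between the
#' empirical CDF of the data and the model CDF of a [dist_spec()].
#'
#' @param values numeric data.
#' @param spec a [dist_spec()] model.
#' @return D in \eqn{[0, 1]}.
#' @seealso [ks_pvalue()] for the asymptotic p-value.
#' @export
ks_distance <- function(values, spec) {
  assert_dist_spec(spec)
  if (!is.numeric(values) || length(values) < 1L || anyNA(values))
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  n <- length(values)
  fx <- cdf(spec, sort(values))
  max(pmax(seq_len(n) / n - fx, fx - (seq_len(n) - 1) / n))
}

#' Asymptotic Kolmogorov-Smirnov p-value
#'
#' Two-sided p-value for an observed KS distance using the asymptotic
#' Kolmogorov distribution
#' \eqn{P(\sqrt n D > z) = 2\sum_{k\ge1} (-1)^{k-1} e^{-2 k^2 z^2}}.
#' Exact small-n p-values are deliberately not provided.
#'
#' @param d observed KS distance.
#' @param n sample size.
#' @return list with `z` (\eqn{= \sqrt n\, d}) and `p_value`.
#' @export
ks_pvalue <- function(d, n) {
  stopifnot(is.numeric(d), d >= 0, is.numeric(n), n >= 1)
  z <- sqrt(n) * d
  if (z < 1e-8) return(list(z = z, p_value = 1))
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * z^2))
  list(z = z, p_value = max(0, min(1, p)))
}

#' Pine-tree counts: number of pine trees in 50 one-acre plots
#'
#' A classic worked example for the Poisson MLE interval: counts of pine
#' trees observed in each of 50 one-acre forest areas. The sample mean is
#' 4.76, giving a 95% interval of about [4.155, 5.365] for the Poisson
#' rate.
#'
#' @return an integer vector of 50 counts.
#' @examples
#' mean(pine_tree_data())  # 4.76
#' @export
pine_tree_data <- function() {
  as.integer(c(7, 4, 5, 3, 1, 5, 7, 6, 4, 3,
               2, 6, 6, 9, 2, 3, 3, 7, 2, 5,
               5, 4, 4, 8, 8, 7, 2, 6, 3, 5,
               0, 5, 8, 9, 3, 4, 5, 4, 6, 1,
               0, 5, 4, 6, 3, 6, 9, 5, 7, 6))
}
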