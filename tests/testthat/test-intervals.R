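# frozen expected values below were derived from the closed forms with
# stats:: quantile functions (independent of the implementation path) or by
# direct summation

test_that("sample_moments computes n, mean, sd and plug-in central moments", {
  m0 <- sample_moments(c(3, 3, 3))
  expect_equal(m0$n, 3L)
  expect_equal(m0$mean, 3)
  expect_equal(m0$sd, 0)
  expect_equal(m0$m4, 0)
  m <- sample_moments(c(1, 2, 3, 4, 5))
  expect_equal(m$mean, 3)
  expect_equal(m$sd, sqrt(2.5))
  expect_equal(m$m2, 2)
  expect_equal(m$m4, 6.8)
  expect_equal(sample_moments(pine_tree_data())$mean, 4.76)
  expect_error(sample_moments(numeric(0)), "non-empty")
})

test_that("mean_ci_z matches the closed form and has data-free width", {
  ci <- mean_ci_z(sample_moments(c(1, 2, 3, 4, 5)), sigma = 1)
  expect_equal(ci$lower, 3 - qnorm(0.975) / sqrt(5))
  expect_equal(ci$upper, 3 + qnorm(0.975) / sqrt(5))
  expect_equal(round(c(ci$lower, ci$upper), 4), c(2.1235, 3.8765))
  # width depends only on (sigma, n, level)
  w1 <- with(mean_ci_z(rnorm(10, 5), sigma = 2), upper - lower)
  w2 <- with(mean_ci_z(rnorm(10, -3, 7), sigma = 2), upper - lower)
  expect_equal(w1, w2)
  expect_equal(w1, 2 * qnorm(0.975) * 2 / sqrt(10))
  # level -> 0 collapses onto the sample mean
  tiny <- mean_ci_z(c(4, 6), sigma = 1, level = 1e-12)
  expect_equal(tiny$lower, 5, tolerance = 1e-9)
  expect_equal(tiny$upper, 5, tolerance = 1e-9)
  expect_error(mean_ci_z(c(1, 2), sigma = 0), "positive")
})

test_that("mean_ci_t matches the closed form and dominates the z-interval", {
  ci <- mean_ci_t(c(1, 2, 3, 4, 5))
  expect_equal(round(c(ci$lower, ci$upper), 4), c(1.0368, 4.9632))
  const <- mean_ci_t(c(2, 2, 2, 2))
  expect_equal(c(const$lower, const$upper), c(2, 2))
  # with sigma set to s, the t-interval strictly contains the z-interval
  for (n in c(2, 5, 20, 100)) {
    x <- rnorm(n, sd = 3)
    if (sd(x) == 0) next
    zi <- mean_ci_z(x, sigma = sd(x))
    ti <- mean_ci_t(x)
    expect_lt(ti$lower, zi$lower)
    expect_gt(ti$upper, zi$upper)
  }
  expect_error(mean_ci_t(5), "n >= 2")
})

test_that("variance_ci_chisquare matches the closed form", {
  ci <- variance_ci_chisquare(c(1, 2, 3, 4, 5))
  expect_equal(ci$lower, 10 / qchisq(0.975, 4))
  expect_equal(ci$upper, 10 / qchisq(0.025, 4))
  expect_equal(round(c(ci$lower, ci$upper), 4), c(0.8974, 20.6433))
  expect_equal(ci$point, 2.5)
  const <- variance_ci_chisquare(rep(7, 6))
  expect_equal(c(const$lower, const$upper), c(0, 0))
  # point estimate always interior (chi-square quantiles straddle the df)
  for (n in c(3, 10, 50)) {
    x <- rexp(n)
    ci <- variance_ci_chisquare(x)
    expect_lt(ci$lower, var(x))
    expect_gt(ci$upper, var(x))
  }
})

test_that("variance_ci_large_sample plugs in the fourth sample moment", {
  ci <- variance_ci_large_sample(c(1, 2, 3, 4, 5))
  hw <- qnorm(0.975) * sqrt((6.8 - 4) / 5)
  expect_equal(c(ci$lower, ci$upper), c(2.5 - hw, 2.5 + hw))
  expect_equal(round(c(ci$lower, ci$upper), 4), c(1.0333, 3.9667))
  const <- variance_ci_large_sample(rep(1, 4))
  expect_equal(c(const$lower, const$upper), c(0, 0))
  # lower bound truncation at 0
  trunc <- variance_ci_large_sample(c(0, 0, 0, 10), level = 0.999)
  expect_identical(trunc$lower, 0)
})

test_that("proportion intervals match their closed forms", {
  z <- qnorm(0.975)
  wald <- proportion_ci_wald(50, 100)
  expect_equal(c(wald$lower, wald$upper), 0.5 + c(-1, 1) * z * 0.05)
  deg <- proportion_ci_wald(0, 10)
  expect_equal(c(deg$lower, deg$upper), c(0, 0))

  wil <- proportion_ci_wilson(50, 100)
  expect_equal(round(c(wil$lower, wil$upper), 5), c(0.40383, 0.59617))
  wil0 <- proportion_ci_wilson(0, 10)
  expect_equal(wil0$lower, 0)
  expect_equal(wil0$upper, z^2 / (10 + z^2))

  cp0 <- proportion_ci_exact(0, 10)
  expect_equal(cp0$lower, 0)
  expect_equal(cp0$upper, 1 - 0.025^(1 / 10))
  expect_equal(proportion_ci_exact(10, 10)$upper, 1)
  expect_error(proportion_ci_wald(11, 10), "cannot exceed")
  expect_error(proportion_ci_wald(-1, 10), "nonnegative")
})

test_that("Clopper-Pearson F form equals the Beta-quantile oracle", {
  for (n in c(1, 5, 17, 60)) {
    for (x in unique(round(c(0, 1, n / 3, n - 1, n)))) {
      if (x < 0 || x > n) next
      ci <- proportion_ci_exact(x, n, level = 0.9)
      lo <- if (x == 0) 0 else qbeta(0.05, x, n - x + 1)
      hi <- if (x == n) 1 else qbeta(0.95, x + 1, n - x)
      expect_equal(ci$lower, lo, tolerance = 1e-10)
      expect_equal(ci$upper, hi, tolerance = 1e-10)
    }
  }
})

test_that("wilson intervals stay in [0,1] and contain the shrunken center", {
  z2 <- qnorm(0.975)^2
  for (n in c(1, 8, 40)) {
    for (x in 0:n) {
      ci <- proportion_ci_wilson(x, n)
      expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
      center <- (x / n + z2 / (2 * n)) / (1 + z2 / n)
      expect_lte(ci$lower, center); expect_gte(ci$upper, center)
    }
  }
})

test_that("raising the level never shrinks any interval", {
  x <- c(0.3, 1.2, 0.8, 2.4, 0.1, 1.9, 0.6, 3.3)
  makers <- list(
    function(l) mean_ci_z(x, sigma = 1, level = l),
    function(l) mean_ci_t(x, level = l),
    function(l) variance_ci_chisquare(x, level = l),
    function(l) variance_ci_large_sample(x, level = l),
    function(l) proportion_ci_wald(3, 8, level = l),
    function(l) proportion_ci_wilson(3, 8, level = l),
    function(l) proportion_ci_exact(3, 8, level = l))
  levels <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  for (mk in makers) {
    cis <- lapply(levels, mk)
    lo <- vapply(cis, `[[`, numeric(1), "lower")
    hi <- vapply(cis, `[[`, numeric(1), "upper")
    expect_true(all(lo <= hi))
    expect_true(all(diff(lo) <= 1e-12))
    expect_true(all(diff(hi) >= -1e-12))
  }
})

test_that("enumeration: exact interval covers >= nominal, Wald collapses near 1", {
  grid <- seq(0.01, 0.99, by = 0.01)
  for (n in c(5, 10, 20, 50)) {
    cov_exact <- vapply(grid, function(p)
      exact_binomial_coverage(n, p, 0.95, "exact"), numeric(1))
    expect_true(all(cov_exact >= 0.95))
  }
  cov_wald <- vapply(grid, function(p)
    exact_binomial_coverage(20, p, 0.95, "wald"), numeric(1))
  expect_lt(min(cov_wald[grid <= 0.05 | grid >= 0.95]), 0.95 - 0.10)
})

test_that("chi-square variance interval: nominal under normal, broken under exponential", {
  cfg_n <- experiment_config(dist_spec("normal", mu = 5, sigma = 2),
                             "variance_chisq", n = 30, level = 0.95,
                             n_intervals = 50, seed = 31)
  meta_n <- run_meta(cfg_n, 120)
  # 3 binomial SEs of the Monte-Carlo design (6000 intervals)
  se <- sqrt(0.95 * 0.05 / (120 * 50))
  expect_lt(abs(meta_n$mean_coverage - 0.95), 3 * se)

  cfg_e <- experiment_config(dist_spec("exponential", rate = 3),
                             "variance_chisq", n = 30, level = 0.95,
                             n_intervals = 50, seed = 32)
  meta_e <- run_meta(cfg_e, 120)
  expect_lt(meta_e$mean_coverage, 0.85)
})
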