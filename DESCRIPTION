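Package: cicover
Title: Confidence Interval Estimators and Monte Carlo Coverage Simulation
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form confidence interval estimators for means, variances
    and proportions (z, t, chi-square, large-sample fourth-moment, Wald,
    Wilson score and exact Clopper-Pearson), asymptotic maximum-likelihood
    intervals from the Fisher information (Poisson rate, exponential rate),
    percentile-bootstrap intervals for arbitrary statistics, and a seeded
    Monte Carlo engine that measures empirical coverage of any of these
    procedures under sampling from six parametric families. Includes an
    exact enumeration oracle for binomial proportion coverage, a
    generalized (four-parameter) Beta maximum-likelihood fit with a
    Kolmogorov-Smirnov distance check, and the curvedness surface-shape
    statistic. A small command-line interface exposes estimation,
    simulation, bootstrapping and model fitting on plain-text data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
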