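test_that("a noiseless power law is recovered exactly by the log-log fit", {
  fit <- fit_size_distribution(power_law_dist(a = -1.28, b = 1.02), "log_log")
  expect_equal(fit$a, -1.28, tolerance = 1e-10)
  expect_equal(fit$b, 1.02, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(predict(fit, c(1, 10)), c(10^1.02, 10^(1.02 - 1.28)),
               tolerance = 1e-10)
})

test_that("a noiseless exponential is recovered exactly by the log-linear fit", {
  fit <- fit_size_distribution(exponential_dist(a = -0.089, b = 0.70),
                               "log_linear")
  expect_equal(fit$a, -0.089, tolerance = 1e-10)
  expect_equal(fit$b, 0.70, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("flat data yield zero slope and the R2 = 0 convention", {
  d <- colony_size_distribution("x", 1:10, rep(5, 10))
  fit <- fit_size_distribution(d, "log_linear")
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$b, log10(5), tolerance = 1e-12)
  expect_equal(fit$r2, 0)
})

test_that("invalid inputs to the fit are rejected", {
  expect_error(fit_size_distribution(
    colony_size_distribution("x", 1:3, c(1, 0, 2)), "log_log"), "> 0")
  expect_error(fit_size_distribution(
    colony_size_distribution("x", 1:2, c(1, 2)), "log_log"), "3 points")
})

test_that("the estimated 1-cell point enters the fit but never the AIC", {
  d <- power_law_dist(f1_estimated = TRUE)
  fit_with <- fit_size_distribution(d, "log_log", include_f1 = TRUE)
  fit_without <- fit_size_distribution(d, "log_log", include_f1 = FALSE)
  expect_equal(fit_with$n_points, 15L)
  expect_equal(fit_without$n_points, 14L)
  expect_false(1L %in% fit_with$aic_sizes)
  expect_false(1L %in% fit_without$aic_sizes)
  expect_identical(fit_with$aic_sizes, fit_without$aic_sizes)
})

test_that("R2 is invariant to rescaling frequencies; slope unchanged", {
  set.seed(31)
  f <- 10^(1 - 1.3 * log10(2:15)) * exp(rnorm(14, sd = 0.1))
  d1 <- colony_size_distribution("x", 2:15, f)
  d2 <- colony_size_distribution("x", 2:15, 7.3 * f)
  f1 <- fit_size_distribution(d1, "log_log")
  f2 <- fit_size_distribution(d2, "log_log")
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
  expect_equal(f1$a, f2$a, tolerance = 1e-12)
  expect_equal(f2$b - f1$b, log10(7.3), tolerance = 1e-12)
})

test_that("AIC decreases with residual sum of squares at fixed N", {
  set.seed(32)
  n <- 2:15
  clean <- 10^(1 - 1.3 * log10(n))
  noisy <- clean * exp(rnorm(14, sd = 0.3))
  aic_clean <- fit_size_distribution(
    colony_size_distribution("x", n, clean * exp(rnorm(14, sd = 0.02))),
    "log_log")$aic
  aic_noisy <- fit_size_distribution(
    colony_size_distribution("x", n, noisy), "log_log")$aic
  expect_lt(aic_clean, aic_noisy)
})

test_that("confidence band has OLS mean-response geometry", {
  set.seed(33)
  n <- 1:15
  d <- colony_size_distribution("x", n,
    10^(1 - 1.2 * log10(n)) * exp(rnorm(15, sd = 0.15)))
  fit <- fit_size_distribution(d, "log_log")
  band <- confidence_band(fit, n)
  expect_true(all(band$lower <= band$fit & band$fit <= band$upper))
  # narrowest (on the log scale) at the design centroid, wider at the ends
  w <- log10(band$upper) - log10(band$lower)
  centroid <- which.min(abs(log10(n) - mean(log10(n))))
  expect_lt(w[centroid], w[1])
  expect_lt(w[centroid], w[15])
  # a higher level widens the band everywhere
  band99 <- confidence_band(fit, n, level = 0.99)
  expect_true(all(log10(band99$upper) - log10(band99$lower) > w))
})

test_that("a perfect fit has a zero-width band", {
  fit <- fit_size_distribution(power_law_dist(), "log_log")
  band <- confidence_band(fit, 1:15)
  expect_equal(band$lower, band$fit, tolerance = 1e-9)
  expect_equal(band$upper, band$fit, tolerance = 1e-9)
})

test_that("AIC selection picks the generating family and flags ties", {
  d_pow <- power_law_dist()
  fits <- list(fit_size_distribution(d_pow, "log_linear"),
               fit_size_distribution(d_pow, "log_log"))
  sel <- aic_compare(fits)
  expect_equal(sel$family, "log_log")
  expect_false(sel$tie)
  d_exp <- exponential_dist()
  sel2 <- aic_compare(list(fit_size_distribution(d_exp, "log_linear"),
                           fit_size_distribution(d_exp, "log_log")))
  expect_equal(sel2$family, "log_linear")
  # identical fits tie; the first-listed family wins and the tie is flagged
  sel3 <- aic_compare(list(fits[[2]], fits[[2]]))
  expect_true(sel3$tie)
  expect_equal(sel3$family, "log_log")
})

test_that("fits over different observation sets are incomparable", {
  f1 <- fit_size_distribution(power_law_dist(n = 1:15), "log_log")
  f2 <- fit_size_distribution(power_law_dist(n = 1:12), "log_log")
  expect_error(aic_compare(list(f1, f2)), "not comparable")
})
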