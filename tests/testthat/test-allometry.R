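test_that("OLS recovers exact lines and matches the normal equations", {
  x <- seq(-1, 2, length.out = 12)
  f <- fit_log_linear_ols(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # closed-form normal-equation oracle on noisy data
  set.seed(11)
  xr <- rnorm(40); yr <- 0.7 * xr + 0.2 + rnorm(40, 0, 0.3)
  f2 <- fit_log_linear_ols(xr, yr)
  sxx <- sum((xr - mean(xr))^2)
  slope <- sum((xr - mean(xr)) * (yr - mean(yr))) / sxx
  expect_equal(f2$slope, slope, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(yr) - slope * mean(xr), tolerance = 1e-10)
  # order invariance
  o <- sample(40)
  f3 <- fit_log_linear_ols(xr[o], yr[o])
  expect_equal(f3$slope, f2$slope, tolerance = 1e-14)
  expect_error(fit_log_linear_ols(rep(1, 5), 1:5), "zero variance")
})

test_that("noiseless data generated from the packaged trunk-rib equation is recovered", {
  row <- equation_record("eq9")
  lx <- seq(2.5, 3.5, length.out = 24)
  ly <- row$slope * lx + row$intercept
  f <- fit_log_linear_ols(lx, ly)
  expect_equal(f$slope, 1.0123, tolerance = 1e-9)
  expect_equal(f$intercept, -0.5068, tolerance = 1e-9)
})

test_that("AICc follows the small-sample correction", {
  expect_equal(aicc(-5, 3, 10), 10 + 6 + 24 / 6)
  expect_equal(aicc(-5, 3, 10), 20)
  expect_equal(aicc(-7, 0, 50), 14)
  expect_lt(abs(aicc(-100, 3, 1e5) - (-2 * -100 + 6)), 1e-3)
  expect_error(aicc(-5, 3, 4), "undefined")
})

test_that("log-logistic fitting recovers the packaged skull-neck curve", {
  row <- equation_record("eq20")
  x <- log10(12:76)
  y <- row$ll_offset + row$ll_numerator / (1 + (x / row$ll_scale)^row$ll_exponent)
  f <- fit_log_logistic(x, y)
  expect_equal(f$numerator, 1.3067, tolerance = 1e-4)
  expect_equal(f$scale, 1.5937, tolerance = 1e-4)
  expect_equal(f$exponent, 10.2847, tolerance = 1e-4)
  expect_equal(f$offset, -1.4684, tolerance = 1e-4)
})

test_that("log-logistic fit flags degenerate flat data and is affine-equivariant", {
  x <- log10(12:40)
  expect_warning(f <- fit_log_logistic(x, rep(0.5, length(x))), "degenerate")
  expect_true(f$degenerate)
  row <- equation_record("eq18")
  y <- row$ll_offset + row$ll_numerator / (1 + (x / row$ll_scale)^row$ll_exponent)
  f1 <- fit_log_logistic(x, y)
  f2 <- fit_log_logistic(x, 2 * y + 0.3)
  expect_equal(f2$numerator, 2 * f1$numerator, tolerance = 1e-3)
  expect_equal(f2$offset, 2 * f1$offset + 0.3, tolerance = 1e-3)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-2)
})

test_that("leave-one-out percent errors match the brute-force refit oracle", {
  set.seed(21)
  for (n in c(8, 14, 20)) {
    x <- runif(n, 2, 4)
    y <- 1.1 * x - 0.4 + rnorm(n, 0, 0.08)
    mine <- loo_prediction_error(x, y)
    oracle <- brute_force_loo(x, y)
    expect_equal(mine$per_sample_pe, oracle$per_sample, tolerance = 1e-10)
    expect_equal(mine$mean_abs_pe, oracle$mean, tolerance = 1e-10)
    expect_equal(mine$sd_abs_pe, oracle$sd, tolerance = 1e-10)
  }
  # perfectly collinear data predict without error
  x <- seq(1, 2, length.out = 10)
  perfect <- loo_prediction_error(x, 3 * x + 0.5)
  expect_equal(perfect$mean_abs_pe, 0, tolerance = 1e-8)
  expect_equal(perfect$sd_abs_pe, 0, tolerance = 1e-8)
  # negative predictions on the comparison scale are an error
  expect_error(
    loo_prediction_error(x, -5 * x, back_transform = identity),
    "non-positive")
})

test_that("prediction intervals are symmetric on the antilog scale", {
  pi1 <- prediction_interval(1000, 17.73)
  expect_equal(pi1$lower, 822.7)
  expect_equal(pi1$upper, 1177.3)
  expect_equal((pi1$lower + pi1$upper) / 2, pi1$point)
  pi0 <- prediction_interval(42, 0)
  expect_equal(pi0$lower, 42)
  expect_equal(pi0$upper, 42)
})

test_that("OLS slope is unbiased under multiplicative lognormal noise", {
  slopes <- vapply(1:200, function(s) {
    d <- gen_allometric_dataset(n = 100, slope = 1.0123, intercept = -0.5068,
                                noise_sigma = 0.05, seed = s)
    fit_log_linear_ols(d$log_x, d$log_y)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.0123), 0.01)
})
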