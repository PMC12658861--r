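make_linear_series <- function(noise_sd = 0, seed = 1, slope = 2,
                               intercept = 3) {
  x <- c(50, 100, 200, 300, 400, 600, 700, 800, 900, 1000)
  y <- intercept + slope * x +
    lcmstats:::with_seed(seed, rnorm(length(x), 0, noise_sd))
  standard_series(x, y, "demo")
}

test_that("weighted least squares recovers exact curves under every weighting", {
  s <- make_linear_series()
  for (w in c("1", "1/x", "1/x^2")) {
    f <- fit_wls(s, "linear", w)
    expect_equal(f$coefficients, c(3, 2), tolerance = 1e-10)
    expect_equal(f$r2, 1, tolerance = 1e-12)
  }
  # parabola: linear underfits, quadratic is exact
  xq <- c(1, 2, 3, 4, 5, 6)
  sq <- standard_series(xq, xq^2)
  expect_lt(fit_wls(sq, "linear", "1")$r2, 1)
  fq <- fit_wls(sq, "quadratic", "1")
  expect_equal(fq$r2, 1, tolerance = 1e-12)
  expect_equal(fq$coefficients, c(0, 0, 1), tolerance = 1e-8)
  expect_lte(fq$adj_r2, fq$r2)
  expect_error(fit_wls(standard_series(1:3, 1:3), "linear", "1"), "at least")
})

test_that("1/x^2 weighting tames heteroscedastic low-end residuals", {
  better <- 0L
  for (r in 1:100) {
    x <- c(50, 100, 200, 300, 400, 600, 700, 800, 900, 1000)
    y <- 2 * x + lcmstats:::with_seed(5000 + r, rnorm(10, 0, 0.05 * x))
    s <- standard_series(x, y)
    low <- x <= 200
    f1 <- fit_wls(s, "linear", "1")
    f2 <- fit_wls(s, "linear", "1/x^2")
    r1 <- sum(residuals(f1$fit)[low]^2)
    r2 <- sum(residuals(f2$fit)[low]^2)
    if (r2 <= r1) better <- better + 1L
  }
  expect_gte(better, 80)
})

test_that("Cook's distance flags the gross outlier and matches the LOO oracle", {
  s <- standard_series(c(1, 2, 3, 4), c(1, 2, 3, 10))
  f <- fit_wls(s, "linear", "1")
  flagged <- detect_outliers(f, "cooks_d")
  expect_true(4 %in% flagged)
  # leave-one-out refit oracle: D_i = sum((yhat - yhat_(i))^2) / (p * s^2)
  fit <- f$fit
  p <- 2; s2 <- sum(residuals(fit)^2) / (4 - p)
  d_oracle <- vapply(1:4, function(i) {
    refit <- lm(y ~ x, data = data.frame(x = s$points$x, y = s$points$y)[-i, ])
    yhat_full <- fitted(fit)
    yhat_loo <- predict(refit, newdata = data.frame(x = s$points$x))
    sum((yhat_full - yhat_loo)^2) / (p * s2)
  }, numeric(1))
  expect_equal(unname(cooks.distance(fit)), d_oracle, tolerance = 1e-10)
  # perfect-fit data -> no flags by any method
  clean <- make_linear_series()
  fc <- fit_wls(clean, "linear", "1")
  expect_length(detect_outliers(fc, "cooks_d"), 0)
  expect_length(detect_outliers(fc, "ci"), 0)
  expect_length(detect_outliers(fc, "bias"), 0)
})

test_that("the bias rule flags 25% back-calculation errors but not 15%", {
  x <- c(100, 200, 300, 400, 500, 600)
  y <- 2 * x
  y[3] <- 2 * (300 * 1.25)  # back-calculates to ~25% relative error
  f <- fit_wls(standard_series(x, y), "linear", "1")
  expect_true(3 %in% detect_outliers(f, "bias"))
  y2 <- 2 * x
  y2[3] <- 2 * (300 * 1.15)
  f2 <- fit_wls(standard_series(x, y2), "linear", "1")
  expect_false(3 %in% detect_outliers(f2, "bias"))
})

test_that("scenario grid retains clean ladders and excises planted outliers", {
  clean <- make_linear_series(noise_sd = 0, slope = 10)
  models <- build_calibration(clean)
  best <- models[[1]]
  expect_length(best$retained_x, 10)
  expect_gt(best$adj_r2, 0.999)
  # gross outlier at one level
  x <- clean$points$x; y <- clean$points$y
  y[5] <- y[5] * 3
  models2 <- build_calibration(standard_series(x, y, "demo"))
  best2 <- models2[[1]]
  expect_equal(best2$removed_x, 400)
  expect_setequal(best2$retained_x, setdiff(x, 400))
  # deterministic ranking: adj R2 desc, then fewer removed, then linear first
  scen <- attr(models2, "scenarios")
  key <- ifelse(is.na(scen$adj_r2), -Inf, scen$adj_r2)
  expect_true(all(diff(key) <= 1e-12))  # adjusted R2 non-increasing
  expect_equal(nrow(scen), 18L)  # 2 forms x 3 weights x 3 methods
})

test_that("noiseless scenarios recover generating coefficients with zero removals", {
  s <- make_linear_series()
  models <- build_calibration(s, forms = "linear")
  for (m in models) {
    expect_true(m$feasible)
    expect_equal(m$coefficients, c(3, 2), tolerance = 1e-8)
    expect_length(m$removed_x, 0)
  }
})

test_that("concentration estimation inverts linear and quadratic curves", {
  s <- make_linear_series()
  m <- build_calibration(s, forms = "linear", weights = "1",
                         methods = "cooks_d")[[1]]
  expect_equal(as.numeric(estimate_concentration(m, 1003)), 500,
               tolerance = 1e-8)
  # quadratic root selection on y = x^2 over [1, 10]
  xq <- seq(1, 10)
  fq <- fit_wls(standard_series(xq, xq^2), "quadratic", "1")
  mq <- lcmstats:::as_calibration_model(fq, outlier_method = "cooks_d")
  expect_equal(as.numeric(estimate_concentration(mq, 49)), 7, tolerance = 1e-6)
  # below-range response -> extrapolation warning
  expect_warning(lo <- estimate_concentration(m, 3), "extrapolat")
  expect_true(attr(lo, "extrapolated"))
  # forward-backward identity on the retained range
  for (x0 in c(60, 350, 990)) {
    y0 <- 3 + 2 * x0
    expect_equal(as.numeric(estimate_concentration(m, y0)), x0,
                 tolerance = 1e-8)
  }
})

test_that("relative errors reproduce the printed test-sample values", {
  expect_equal(relative_error(507.4039, 500), 1.4808, tolerance = 1e-4)
  expect_equal(relative_error(499.5544, 500), -0.0891, tolerance = 1e-3)
  expect_equal(relative_error(500, 500), 0)
  expect_error(relative_error(1, 0), "> 0")
})

test_that("planted 10x outliers are caught by all three rules almost always", {
  caught <- c(cooks_d = 0L, ci = 0L, bias = 0L)
  n_rep <- 200
  for (r in 1:n_rep) {
    x <- seq(10, 100, by = 10)
    noise <- lcmstats:::with_seed(9000 + r, rnorm(10, 0, 8))
    y <- 5 + 2 * x + noise
    i_out <- (r %% 10) + 1
    y[i_out] <- y[i_out] + sign(noise[i_out] + 0.1) * 10 * 8
    f <- fit_wls(standard_series(x, y), "linear", "1")
    for (m in names(caught)) {
      fl <- detect_outliers(f, m)
      if (i_out %in% fl) caught[[m]] <- caught[[m]] + 1L
    }
  }
  for (m in names(caught)) expect_gte(caught[[m]], 0.95 * n_rep)
})
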