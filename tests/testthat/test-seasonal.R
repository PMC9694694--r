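test_that("concatenated cluster series have length S x n and keep missing markers", {
  set <- generate_pp_set(K = 2, n_per_cluster = 8, noise_sd = 4, seed = 19)
  X <- set$X
  X[3, 40:48] <- NA # padded tail
  pps <- pp_set_from_matrix(X, presamples = c(NA, NA, 110, 112, 111))
  fit <- pdsfcm(X, 2, m = 2, seed = 2)

  for (i in 1:2) {
    ser <- build_seasonal_series(pps, fit, i)
    expect_equal(length(ser) %% 53, 0)
    expect_equal(length(ser), 53 * attr(ser, "n_pp"))
    # every block starts with the presample pattern incl. its missing markers
    first_block <- ser[1:53]
    expect_true(is.na(first_block[1]) && is.na(first_block[2]))
    expect_equal(first_block[3:5], c(110, 112, 111))
  }

  one <- pp_set_from_matrix(X[1, , drop = FALSE])
  single_fit <- structure(
    list(n_clusters = 1L, fuzzifier = 2,
         prototypes = matrix(colMeans(X, na.rm = TRUE), 1),
         memberships = matrix(1, 1, 1)),
    class = "pdsfcm"
  )
  expect_equal(length(build_seasonal_series(one, single_fit, 1)), 53)
  expect_error(build_seasonal_series(one, single_fit, 2), "hard-assigned")
})

test_that("maximum-likelihood SARIMA fits recover simulated coefficients", {
  # 2-SE intervals have ~95% coverage, so a single simulated draw can
  # legitimately miss; check coverage over 5 seeds instead (>= 4/5 inside).
  hits_ar <- hits_wn <- 0
  for (seed in 1:5) {
    set.seed(400 + seed)
    y <- as.numeric(arima.sim(list(ar = 0.7), n = 2000)) * 10 + 120
    fit <- fit_sarima(y, c(1, 0, 0), c(0, 0, 0), s = 53)
    expect_true(fit$converged)
    hits_ar <- hits_ar + (abs(fit$coef["ar1"] - 0.7) < 2 * fit$se["ar1"])

    # white noise fit with seasonal terms: coefficients near 0
    wn <- rnorm(1200, 100, 10)
    fit_wn <- fit_sarima(wn, c(1, 0, 0), c(1, 0, 0), s = 10)
    hits_wn <- hits_wn + (abs(fit_wn$coef["ar1"]) < 2 * fit_wn$se["ar1"] &&
                            abs(fit_wn$coef["sar1"]) < 2 * fit_wn$se["sar1"])
  }
  expect_gte(hits_ar, 4)
  expect_gte(hits_wn, 4)

  # determinism: identical series -> identical BIC
  set.seed(401)
  y <- as.numeric(arima.sim(list(ar = 0.7), n = 2000)) * 10 + 120
  fit <- fit_sarima(y, c(1, 0, 0), c(0, 0, 0), s = 53)
  fit2 <- fit_sarima(y, c(1, 0, 0), c(0, 0, 0), s = 53)
  expect_identical(fit$bic, fit2$bic)
  expect_identical(fit$coef, fit2$coef)

  # missing values are handled by the filter, not imputed
  y_na <- y
  y_na[sample(2000, 200)] <- NA
  fit_na <- fit_sarima(y_na, c(1, 0, 0), c(0, 0, 0), s = 53)
  expect_true(fit_na$converged)
  expect_lt(abs(fit_na$coef["ar1"] - 0.7), 3 * fit_na$se["ar1"])
})

test_that("BIC grid search finds seasonal structure and respects ties", {
  # SARIMA(1,0,0)(1,0,0)_10: (1 - 0.6 B)(1 - 0.5 B^10) y = e
  set.seed(403)
  ar_poly <- c(0.6, rep(0, 8), 0.5, -0.3)
  y <- as.numeric(arima.sim(list(ar = ar_poly), n = 3000))
  grid <- sarima_grid(p = 1:2, q = 0:1, d = 0, P = 0:1, Q = 0, D = 0)
  best <- select_sarima(y, grid, s = 10)
  expect_gte(best$order[1], 1)
  expect_equal(best$seasonal_order[1], 1)
  nonseasonal <- fit_sarima(y, c(1, 0, 1), c(0, 0, 0), s = 10)
  expect_lt(best$bic, nonseasonal$bic)
  expect_lt(abs(best$coef["ar1"] - 0.6), 2 * best$se["ar1"])
  expect_lt(abs(best$coef["sar1"] - 0.5), 2 * best$se["sar1"])

  # the selected model minimises BIC over every converged alternative
  search <- attr(best, "search")
  expect_true(all(best$bic <= search$bic[search$converged] + 1e-9))

  # a one-cell grid returns that cell
  one <- select_sarima(y, sarima_grid(p = 1, q = 0, d = 0, P = 1, Q = 0, D = 0), s = 10)
  expect_equal(one$order, c(1L, 0L, 0L))
  expect_equal(one$seasonal_order, c(1L, 0L, 0L))
})

test_that("forecasts match closed forms and converge to the mean", {
  # AR(1), mean 0, phi = 0.5, last value 10: h-step forecast = 0.5^h * 10
  spec <- ar1_spec(phi = 0.5, mean = 0)
  f <- sarima_forecast(spec, c(rep(0, 10), 10), 4)
  expect_equal(f, 0.5^(1:4) * 10, tolerance = 1e-6)

  # random walk: every horizon repeats the last observed value
  rw <- rw_spec()
  expect_equal(sarima_forecast(rw, c(100, 104, 101, NA, 107), 6),
               rep(107, 6), tolerance = 1e-8)

  # stationary model: long-horizon forecast approaches the fitted mean
  spec2 <- ar1_spec(phi = 0.8, mean = 120)
  f2 <- sarima_forecast(spec2, c(120, 130, 150), 60)
  expect_equal(f2[60], 120, tolerance = 1e-3)
  expect_true(all(diff(abs(f2 - 120)) <= 1e-9))

  # empty or all-missing history falls back to the unconditional level
  f3 <- sarima_forecast(spec2, numeric(0), 3)
  expect_equal(as.numeric(f3), rep(120, 3))
  expect_true(attr(f3, "unconditional"))
  f4 <- sarima_forecast(spec2, rep(NA_real_, 5), 2)
  expect_true(attr(f4, "unconditional"))

  expect_error(sarima_forecast(spec2, c(1, 2), 0), "h")
})

test_that("one-step AR(1) forecast matches the conditional-mean closed form", {
  # with a fully observed AR(1) history the filter's one-step prediction has
  # the closed form alpha + phi * (y_T - alpha), independent of the filter
  spec <- ar1_spec(phi = 0.62, mean = 118)
  y <- c(120, 131, 142, 128, 114)
  f <- sarima_forecast(spec, y, 3)
  expect_equal(f[1], 118 + 0.62 * (114 - 118), tolerance = 1e-8)
  expect_equal(f[2], 118 + 0.62^2 * (114 - 118), tolerance = 1e-8)

  # and with the final sample missing, conditioning skips it: the forecast
  # for t+1 is the two-step prediction from the last observed value
  f_na <- sarima_forecast(spec, c(y, NA), 1)
  expect_equal(f_na[1], 118 + 0.62^2 * (114 - 118), tolerance = 1e-8)
})
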