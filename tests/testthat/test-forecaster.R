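# A two-cluster bundle around hand-built AR(1) local models: cheap enough to
# replay many steps, expressive enough to exercise the weighting logic.
two_cluster_bundle <- function() {
  manual_bundle(
    prototypes = rbind(rep(100, 48), rep(200, 48)),
    models = list(ar1_spec(phi = 0.6, mean = 100),
                  ar1_spec(phi = 0.6, mean = 200))
  )
}

test_that("horizons convert to steps and invalid horizons are rejected", {
  b <- two_cluster_bundle()
  st <- start_pp(rep(110, 5), b, ph_minutes = c(30, 45, 60, 75))
  expect_equal(st$ph_steps, c(6L, 9L, 12L, 15L))
  expect_null(st$output)
  expect_error(start_pp(rep(110, 5), b, ph_minutes = 7), "multiple")
})

test_that("no output before the 3rd observed sample; missing extends the wait", {
  b <- two_cluster_bundle()
  st <- start_pp(rep(110, 5), b, ph_minutes = 30)
  st <- step_pp(st, 120)
  expect_null(st$output)
  st <- step_pp(st, NA) # missing: does not count toward burn-in
  expect_null(st$output)
  st <- step_pp(st, 125)
  expect_null(st$output)
  st <- step_pp(st, 130) # 3rd observed sample
  expect_false(is.null(st$output))
  expect_named(st$output, "30")

  # stepping past the window is an error
  st48 <- start_pp(rep(110, 5), b, 30)
  for (k in 1:48) st48 <- step_pp(st48, 110)
  expect_error(step_pp(st48, 110), "closed")
})

test_that("with a single cluster the loop reduces to plain SARIMA forecasting", {
  model <- ar1_spec(phi = 0.7, mean = 150)
  b1 <- manual_bundle(prototypes = matrix(150, 1, 48), models = list(model))
  pre <- c(140, 142, 138, 145, 143)
  window <- c(150, 160, 170, 165, 168, 172)
  pp <- list(window = c(window, rep(NA, 42)), presamples = pre,
             meal_index = 1L, observed_length = 6L)
  got <- predict_pp(pp, b1, ph_minutes = c(30, 60))
  for (t in 3:6) {
    direct <- sarima_forecast(model, c(pre, window[1:t]), 12)
    expect_equal(got$y_hat[got$slot == t & got$ph_minutes == 30], direct[6],
                 tolerance = 1e-10)
    expect_equal(got$y_hat[got$slot == t & got$ph_minutes == 60], direct[12],
                 tolerance = 1e-10)
  }
})

test_that("the output is a convex combination of the local forecasts", {
  b <- two_cluster_bundle()
  st <- start_pp(rep(110, 5), b, ph_minutes = c(30, 75))
  obs <- c(120, 135, 150, 170, NA, 180)
  for (x in obs) {
    st <- step_pp(st, x)
    if (!is.null(st$output)) {
      lo <- apply(st$local_predictions, 2, min)
      hi <- apply(st$local_predictions, 2, max)
      expect_true(all(st$output >= lo - 1e-9 & st$output <= hi + 1e-9))
      expect_equal(sum(st$weights), 1, tolerance = 1e-9)
    }
  }
})

test_that("relabelling the clusters leaves the output unchanged", {
  b <- two_cluster_bundle()
  b_perm <- b
  b_perm$cluster_set$prototypes <- b$cluster_set$prototypes[2:1, ]
  b_perm$models <- b$models[2:1]
  pp <- list(window = c(112, 125, 150, 163, 170, rep(NA, 43)),
             presamples = rep(108, 5), meal_index = 1L, observed_length = 5L)
  # up to BLAS summation order in the weighted combination
  expect_equal(predict_pp(pp, b)$y_hat, predict_pp(pp, b_perm)$y_hat,
               tolerance = 1e-12)
})

test_that("an equidistant prefix averages the two local forecasts", {
  b <- two_cluster_bundle()
  pp <- list(window = c(150, 150, 150, rep(NA, 45)), presamples = rep(150, 5),
             meal_index = 1L, observed_length = 3L)
  got <- predict_pp(pp, b, ph_minutes = 30)
  f1 <- sarima_forecast(b$models[[1]], rep(150, 8), 6)[6]
  f2 <- sarima_forecast(b$models[[2]], rep(150, 8), 6)[6]
  expect_equal(got$y_hat, (f1 + f2) / 2, tolerance = 1e-9)
})

test_that("prediction/target pairing respects the window and burn-in arithmetic", {
  b <- two_cluster_bundle()
  window <- rep(NA_real_, 48)
  window[1:20] <- seq(120, 215, by = 5)
  pp <- list(window = window, presamples = rep(115, 5),
             meal_index = 7L, observed_length = 20L)

  got <- predict_pp(pp, b, ph_minutes = 75) # 15 steps ahead
  # outputs exist from the burn-in (slot 3) to the end of the observed region
  expect_equal(sort(unique(got$slot)), 3:20)
  # but targets exist only while t + 15 <= 20, i.e. t in 3..5
  paired <- got[!is.na(got$target), ]
  expect_equal(sort(paired$slot), 3:5)
  expect_equal(paired$target, window[paired$slot + 15])

  # an empty horizon list yields an empty result
  expect_equal(nrow(predict_pp(pp, b, ph_minutes = integer(0))), 0)
})

test_that("model bundles round-trip through JSON", {
  b <- two_cluster_bundle()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model_bundle(b, tmp)
  back <- read_model_bundle(tmp)
  expect_equal(back$cluster_set$prototypes, b$cluster_set$prototypes)
  expect_equal(back$models[[2]]$coef, b$models[[2]]$coef)
  expect_equal(back$s, b$s)

  pp <- list(window = c(130, 150, 170, rep(NA, 45)), presamples = rep(120, 5),
             meal_index = 1L, observed_length = 3L)
  expect_equal(predict_pp(pp, back, 30)$y_hat, predict_pp(pp, b, 30)$y_hat,
               tolerance = 1e-12)
})
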