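test_that("per-PP RMSE matches hand values and a brute-force oracle", {
  expect_equal(rmse_pp(c(100, 110), c(100, 110)), 0)
  expect_equal(rmse_pp(c(100, 110, 120), c(105, 115, 125)), 5)
  expect_equal(rmse_pp(c(100, 110), c(100, 120)), sqrt(50))

  brute <- function(target, prediction) {
    acc <- 0
    n <- 0
    for (k in seq_along(target)) {
      if (!is.na(target[k]) && !is.na(prediction[k])) {
        acc <- acc + (target[k] - prediction[k])^2
        n <- n + 1
      }
    }
    sqrt(acc / n)
  }
  set.seed(91)
  for (rep in 1:20) {
    tg <- rnorm(30, 150, 40)
    pr <- tg + rnorm(30, 0, 15)
    tg[sample(30, 5)] <- NA
    pr[sample(30, 5)] <- NA
    expect_equal(rmse_pp(tg, pr), brute(tg, pr), tolerance = 1e-12)
  }

  expect_true(is.na(suppressMessages(rmse_pp(c(NA, NA), c(1, NA)))))
  expect_error(rmse_pp(1:3, 1:2), "equal length")
})

test_that("aggregation follows median-of-medians with linear-interpolation quartiles", {
  # per-PP rmse {1,2,3} for one subject
  pred <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(subject = 1L, method = "A", meal_index = i, ph_minutes = 30,
                   slot = 3, y_hat = 100, target = 100 + i)
  })
  ev <- evaluate_predictions(pred)
  expect_equal(ev$per_subject$median_rmse, 2)
  expect_equal(ev$cohort$median, 2)

  # two subjects with medians 10 and 20 -> cohort median 15
  pred2 <- dplyr::bind_rows(
    tibble::tibble(subject = 1L, method = "A", meal_index = 1, ph_minutes = 30,
                   slot = 3, y_hat = 100, target = 110),
    tibble::tibble(subject = 2L, method = "A", meal_index = 1, ph_minutes = 30,
                   slot = 3, y_hat = 100, target = 120)
  )
  expect_equal(evaluate_predictions(pred2)$cohort$median, 15)

  # quartile convention on subject medians {1,2,3,4}
  pred4 <- purrr::map_dfr(1:4, function(s) {
    tibble::tibble(subject = s, method = "A", meal_index = 1, ph_minutes = 30,
                   slot = 3, y_hat = 100, target = 100 + s)
  })
  co <- evaluate_predictions(pred4)$cohort
  expect_equal(co$q1, 1.75)
  expect_equal(co$q3, 3.25)

  # PP order does not matter
  shuffled <- pred4[sample(nrow(pred4)), ]
  expect_equal(evaluate_predictions(shuffled)$cohort, co)

  # a PP with no valid pair is dropped, not zero-filled
  with_empty <- dplyr::bind_rows(
    pred,
    tibble::tibble(subject = 1L, method = "A", meal_index = 9, ph_minutes = 30,
                   slot = 3, y_hat = 100, target = NA_real_)
  )
  expect_equal(nrow(suppressMessages(evaluate_predictions(with_empty))$per_pp), 3)
})

test_that("method comparison gates on normality and handles degenerate input", {
  a <- c(20, 22, 25, 19, 23, 21, 24, 20, 22, 23, 21)

  same <- compare_methods(a, a)
  expect_false(same$significant)
  expect_equal(same$p_value, 1)

  # a large constant shift with small jitter is detected
  set.seed(92)
  b <- a + 10 + rnorm(11, 0, 0.5)
  res <- compare_methods(a, b)
  expect_true(res$significant)

  # heavy-tailed differences send the test down the Wilcoxon branch
  set.seed(93)
  d <- rt(15, df = 1) * 5
  res_t <- compare_methods(a[1] + d, rep(a[1], 15))
  expect_equal(res_t$test, "Wilcoxon signed-rank")

  # p-value is symmetric in the argument order
  res_ab <- compare_methods(a, b)
  res_ba <- compare_methods(b, a)
  expect_equal(res_ab$p_value, res_ba$p_value, tolerance = 1e-12)
  expect_identical(res_ab$test, res_ba$test)

  expect_error(compare_methods(a[1:2], a[1:2]), "3")
})

test_that("pairwise comparisons run per horizon across methods", {
  set.seed(94)
  ps <- tidyr::expand_grid(subject = 1:8, method = c("A", "B"),
                           ph_minutes = c(30, 60))
  ps$median_rmse <- ifelse(ps$method == "B", 25, 18) + rnorm(nrow(ps), 0, 1)
  ev <- structure(list(per_subject = ps), class = "csarima_eval")
  cmp <- compare_all_methods(ev)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$significant))
  expect_true(all(cmp$method_a == "A" & cmp$method_b == "B"))
})
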