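#' Align meal and insulin events onto the CGM grid as exogenous signals
#'
#' Carbohydrates and boluses are encoded as raw impulses: the full logged
#' amount is placed in the event's grid slot and zero elsewhere (no
#' absorption or insulin-action curves — the minimal faithful encoding of
#' "timing and amount"). Basal records are rate changes: each sets the IU/h
#' rate from its slot until the next basal record, contributing rate / 12 IU
#' per 5-minute slot, added to the insulin signal. Meals with unknown
#' amounts contribute zero carbohydrates.
#'
#' @param events an [event_log()].
#' @param series the [glucose_series()] defining the grid.
#' @return Tibble with columns `time`, `cho` (g per slot), `insulin` (IU per
#'   slot), one row per grid slot of `series`.
#' @export
build_exog_signals <- function(events, series) {
  n <- nrow(series)
  step_min <- sampling_minutes(series)
  step_sec <- step_min * 60
  cho <- numeric(n)
  insulin <- numeric(n)
  slot_of <- function(t) snap_to_grid(t, series$time[1], step_sec) + 1L
  place <- function(rows, target) {
    s <- slot_of(rows$time)
    ok <- s >= 1L & s <= n
    amt <- ifelse(is.na(rows$amount), 0, rows$amount)
    for (k in which(ok)) target[s[k]] <- target[s[k]] + amt[k]
    target
  }
  cho <- place(events[events$kind == "meal", ], cho)
  insulin <- place(events[events$kind == "bolus", ], insulin)
  basal <- events[events$kind == "basal", ]
  if (nrow(basal) > 0) {
    s <- pmax(1L, pmin(n + 1L, slot_of(basal$time)))
    bounds <- c(s, n + 1L)
    for (k in seq_len(nrow(basal))) {
      from <- bounds[k]
      to <- bounds[k + 1L] - 1L
      if (from <= to && from <= n) {
        rate <- ifelse(is.na(basal$amount[k]), 0, basal$amount[k])
        idx <- from:min(to, n)
        insulin[idx] <- insulin[idx] + rate * step_min / 60
      }
    }
  }
  tibble::tibble(time = series$time, cho = cho, insulin = insulin)
}

# Distributed-lag design matrix: lags 0..(x_lag - 1) of each signal column;
# values before the series start are zero (no event recorded).
lag_matrix <- function(exog, x_lag) {
  cols <- purrr::map(c("cho", "insulin"), function(nm) {
    v <- exog[[nm]]
    sapply(0:(x_lag - 1L), function(l) c(rep(0, l), head(v, length(v) - l)))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- c(paste0("cho_l", 0:(x_lag - 1L)),
                     paste0("ins_l", 0:(x_lag - 1L)))
  out
}

#' Benchmark identification grid
#'
#' Default explored orders for the individualized comparators: AR 1..20,
#' MA 0..20, differencing 0..1, and distributed-lag order 1..20 for the
#' exogenous inputs (ARIMAX only).
#'
#' @param ar,ma,i,x integer vectors of candidate orders.
#' @return A list of class `benchmark_grid`.
#' @export
benchmark_grid <- function(ar = 1:20, ma = 0:20, i = 0:1, x = 1:20) {
  structure(list(ar = ar, ma = ma, i = i, x = x), class = "benchmark_grid")
}

# Fit one ARIMA(X) cell. Constant exogenous columns are dropped before
# estimation (their coefficients are unidentifiable and contribute nothing
# to forecasts) and reported with coefficient zero.
fit_arimax_once <- function(y, order, xreg = NULL) {
  include_mean <- order[2] == 0
  kept <- NULL
  if (!is.null(xreg)) {
    kept <- which(apply(xreg, 2, function(col) stats::sd(col) > 0))
    xreg_fit <- if (length(kept) > 0) xreg[, kept, drop = FALSE] else NULL
  } else {
    xreg_fit <- NULL
  }
  fit <- tryCatch(
    stats::arima(y, order = order, xreg = xreg_fit,
                 include.mean = include_mean, method = "ML"),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(converged = FALSE, bic = Inf, message = conditionMessage(fit)))
  }
  co <- stats::coef(fit)
  if (!is.null(xreg)) {
    full <- setNames(rep(0, ncol(xreg)), colnames(xreg))
    full[colnames(xreg)[kept]] <- co[colnames(xreg)[kept]]
    co <- c(co[setdiff(names(co), colnames(xreg))], full)
  }
  n_eff <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1
  list(converged = isTRUE(fit$code == 0), coef = co, sigma2 = fit$sigma2,
       loglik = fit$loglik, bic = k * log(n_eff) - 2 * fit$loglik,
       n_obs = n_eff, include_mean = include_mean)
}

#' Fit an individualized ARIMA or ARIMAX benchmark
#'
#' Two-phase protocol: the model *orders* are selected once by summing each
#' grid cell's BIC across all supplied subjects and taking the argmin (with
#' a single subject this reduces to that subject's BIC), then the
#' *coefficients* are re-estimated per subject at the fixed orders. Supply
#' exogenous signals (from [build_exog_signals()]) to fit the ARIMAX, whose
#' carbohydrate and insulin inputs enter through distributed lags of order
#' `x`; omit them for the CGM-only ARIMA.
#'
#' @param train a [glucose_series()] or a list of them (one per subject).
#' @param exog matching exogenous-signal tibble(s) or `NULL` for ARIMA.
#' @param grid a [benchmark_grid()].
#' @return An object of class `benchmark_fit`: `kind`, `order`
#'   (AR, I, MA), `x_lag`, `fits` (per-subject coefficient sets), and the
#'   order-search table as attribute `search`.
#' @export
fit_benchmark <- function(train, exog = NULL, grid = benchmark_grid()) {
  if (inherits(train, "glucose_series")) train <- list(train)
  kind <- if (is.null(exog)) "ARIMA" else "ARIMAX"
  if (!is.null(exog) && !is.data.frame(exog[[1]])) exog <- list(exog)
  ys <- purrr::map(train, function(s) as.numeric(s$glucose))
  xlags <- if (kind == "ARIMAX") grid$x else 0L
  cells <- expand.grid(ar = grid$ar, i = grid$i, ma = grid$ma, x = xlags)
  rows <- purrr::map(seq_len(nrow(cells)), function(k) {
    order <- c(cells$ar[k], cells$i[k], cells$ma[k])
    bics <- purrr::map_dbl(seq_along(ys), function(j) {
      xr <- if (kind == "ARIMAX") lag_matrix(exog[[j]], cells$x[k]) else NULL
      fit_arimax_once(ys[[j]], order, xr)$bic
    })
    tibble::tibble(ar = cells$ar[k], i = cells$i[k], ma = cells$ma[k],
                   x = cells$x[k], total_bic = sum(bics))
  })
  search <- dplyr::bind_rows(rows)
  ok <- which(is.finite(search$total_bic))
  if (length(ok) == 0) abort("No benchmark grid cell converged for all subjects.")
  n_par <- with(search, ar + ma + ifelse(x > 0, 2 * x, 0))
  best <- ok[order(search$total_bic[ok], n_par[ok],
                   search$ar[ok], search$i[ok], search$ma[ok], search$x[ok])][1]
  order <- c(search$ar[best], search$i[best], search$ma[best])
  x_lag <- search$x[best]
  fits <- purrr::map(seq_along(ys), function(j) {
    xr <- if (kind == "ARIMAX") lag_matrix(exog[[j]], x_lag) else NULL
    f <- fit_arimax_once(ys[[j]], order, xr)
    if (!f$converged) warn(sprintf("Benchmark re-estimation did not converge for subject %d.", j))
    f
  })
  structure(list(kind = kind, order = order, x_lag = x_lag, fits = fits),
            class = "benchmark_fit", search = search)
}

#' @export
print.benchmark_fit <- function(x, ...) {
  cat(sprintf("<benchmark_fit> %s(%s)%s, %d subject(s)\n", x$kind,
              paste(x$order, collapse = ","),
              if (x$kind == "ARIMAX") sprintf(" with %d exogenous lags", x$x_lag) else "",
              length(x$fits)))
  invisible(x)
}

# Forecast h steps from a fitted benchmark given an explicit history (and,
# for ARIMAX, the matching past and future exogenous rows). Coefficients are
# fixed; only the Kalman state is conditioned on the history.
benchmark_forecast <- function(model, subject_fit, history, h,
                               xreg_past = NULL, xreg_future = NULL) {
  refit <- tryCatch(
    suppressWarnings(
      stats::arima(history, order = model$order, xreg = xreg_past,
                   include.mean = subject_fit$include_mean,
                   fixed = subject_fit$coef, transform.pars = FALSE,
                   method = "ML")
    ),
    error = function(e) e
  )
  if (inherits(refit, "error")) {
    last <- if (any(!is.na(history))) history[max(which(!is.na(history)))] else NA_real_
    return(structure(rep(last, h), unconditional = TRUE))
  }
  as.numeric(stats::predict(refit, n.ahead = h, newxreg = xreg_future)$pred)
}

#' Benchmark predictions over the test postprandial periods
#'
#' Unlike the meal-reset C-SARIMA loop, the benchmarks condition on the full
#' test-series history up to each forecast origin. Future exogenous values
#' within the horizon are taken from the event log — meals and boluses are
#' announced at mealtime, so this is known information for the ARIMAX (an
#' information advantage it is meant to have). Predictions are produced at
#' exactly the slots where the C-SARIMA produces them (after 3 observed
#' post-meal samples) and paired with targets by the same arithmetic, so
#' both methods are evaluated on identical pairs.
#'
#' @param model a [fit_benchmark()] object.
#' @param series the test [glucose_series()].
#' @param pps the test `pp_set` (segmented from `series`).
#' @param events the test [event_log()] (required for ARIMAX).
#' @param ph_minutes prediction horizons in minutes.
#' @param subject index of the per-subject coefficient set to use.
#' @param burn_in observed post-meal samples required before predicting.
#' @return Long tibble (`meal_index`, `slot`, `ph_minutes`, `y_hat`,
#'   `target`, `method`).
#' @export
predict_pp_benchmark <- function(model, series, pps, events = NULL,
                                 ph_minutes = c(30, 45, 60, 75),
                                 subject = 1L, burn_in = 3L) {
  ph_steps <- validate_ph(ph_minutes, sampling_minutes(series))
  if (length(ph_steps) == 0) {
    return(tibble::tibble(meal_index = integer(), slot = integer(),
                          ph_minutes = integer(), y_hat = double(),
                          target = double(), method = character()))
  }
  sf <- model$fits[[subject]]
  y <- as.numeric(series$glucose)
  xreg <- NULL
  if (model$kind == "ARIMAX") {
    if (is.null(events)) abort("ARIMAX prediction needs the test event log.")
    sig <- build_exog_signals(events, series)
    xreg <- lag_matrix(sig, model$x_lag)
  }
  h <- max(ph_steps)
  pad_future <- function(from) {
    idx <- from:(from + h - 1L)
    out <- matrix(0, h, ncol(xreg), dimnames = list(NULL, colnames(xreg)))
    ok <- idx <= nrow(xreg)
    out[ok, ] <- xreg[idx[ok], , drop = FALSE]
    out
  }
  out <- purrr::map(seq_len(nrow(pps)), function(j) {
    window <- pps$window[[j]]
    meal_slot <- pps$slot[j]
    n_obs_prefix <- cumsum(!is.na(window[seq_len(pps$observed_length[j])]))
    rows <- purrr::map(seq_len(pps$observed_length[j]), function(t) {
      if (n_obs_prefix[t] < burn_in) return(NULL)
      origin <- meal_slot + t - 1L
      yh <- benchmark_forecast(
        model, sf, y[seq_len(origin)], h,
        xreg_past = if (!is.null(xreg)) xreg[seq_len(origin), , drop = FALSE],
        xreg_future = if (!is.null(xreg)) pad_future(origin + 1L)
      )[ph_steps]
      tibble::tibble(meal_index = pps$meal_index[j], slot = t,
                     ph_minutes = as.integer(ph_minutes), y_hat = yh,
                     target = pp_target_at(window, t, ph_steps))
    })
    dplyr::bind_rows(purrr::compact(rows))
  })
  dplyr::mutate(dplyr::bind_rows(out), method = model$kind)
}
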