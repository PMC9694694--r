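#' Construct a uniformly sampled CGM series
#'
#' A glucose series is a tibble with one row per slot of a uniform sampling
#' grid: column `time` (POSIXct) and column `glucose` (mg/dL, `NA` where the
#' sensor reading is missing). The sampling interval (default 5 minutes, the
#' native rate of the CGM devices this package targets) is stored as an
#' attribute so downstream slot arithmetic never has to re-derive it.
#'
#' @param time POSIXct vector on a uniform grid, strictly increasing.
#' @param glucose numeric vector of glucose values in mg/dL; `NA` = missing.
#' @param sampling_minutes grid spacing in minutes.
#' @return A tibble of class `glucose_series` with columns `time`, `glucose`.
#' @examples
#' t0 <- as.POSIXct("2023-01-01 08:00:00", tz = "UTC")
#' glucose_series(t0 + seq(0, 600, by = 300), c(100, NA, 130))
#' @export
glucose_series <- function(time, glucose, sampling_minutes = 5) {
  if (length(time) != length(glucose)) {
    abort("`time` and `glucose` must have equal length.")
  }
  if (!inherits(time, "POSIXct")) {
    abort("`time` must be POSIXct.")
  }
  glucose <- as.double(glucose)
  bad <- !is.na(glucose) & (!is.finite(glucose) | glucose <= 0)
  if (any(bad)) {
    abort(sprintf("Non-missing glucose values must be finite and > 0 (first offender at row %d).",
                  which(bad)[1]))
  }
  step <- sampling_minutes * 60
  if (length(time) > 1) {
    d <- diff(as.numeric(time))
    if (any(abs(d - step) > 1e-6)) {
      abort("`time` must lie on a uniform grid with the stated sampling interval.")
    }
  }
  out <- tibble::tibble(time = time, glucose = glucose)
  attr(out, "sampling_minutes") <- sampling_minutes
  class(out) <- c("glucose_series", class(out))
  out
}

#' @export
print.glucose_series <- function(x, ...) {
  n_miss <- sum(is.na(x$glucose))
  cat(sprintf("<glucose_series> %d slots at %g min, %.1f%% missing\n",
              nrow(x), sampling_minutes(x), 100 * n_miss / max(1L, nrow(x))))
  NextMethod()
}

sampling_minutes <- function(series) {
  attr(series, "sampling_minutes") %||% 5
}

# Rebuild a glucose_series from a plain tibble slice, keeping the attribute.
as_glucose_series <- function(df, sampling_minutes = 5) {
  glucose_series(df$time, df$glucose, sampling_minutes)
}

# Index of the grid slot nearest to `t`, given the grid origin and step.
# Ties (exactly halfway between slots) snap to the earlier slot: CGM clock
# drift has no preferred direction, so the choice is a documented convention.
snap_to_grid <- function(t, origin, step_sec) {
  ceiling(as.numeric(t - origin, units = "secs") / step_sec - 0.5)
}

#' Summarise glycemic control of a CGM series
#'
#' Computes the standard ambulatory glucose metrics over the non-missing
#' samples: the coefficient of variation CV = 100 * sd / mean, time below
#' range (< 70 mg/dL), time in range (70-180 mg/dL), time above range
#' (> 180 mg/dL), and the fraction of missing samples.
#'
#' @param series a [glucose_series()].
#' @return One-row tibble with columns `cv`, `tbr`, `tir`, `tar`,
#'   `missing_pct` (all percentages).
#' @examples
#' t0 <- as.POSIXct("2023-01-01", tz = "UTC")
#' s <- glucose_series(t0 + seq(0, 300 * 2, by = 300), c(60, 100, 200))
#' glycemic_summary(s)
#' @export
glycemic_summary <- function(series) {
  g <- series$glucose
  obs <- g[!is.na(g)]
  if (length(obs) == 0) {
    abort("Cannot summarise an all-missing glucose series.")
  }
  tibble::tibble(
    cv = 100 * stats::sd(obs) / mean(obs),
    tbr = 100 * mean(obs < 70),
    tir = 100 * mean(obs >= 70 & obs <= 180),
    tar = 100 * mean(obs > 180),
    missing_pct = 100 * mean(is.na(g))
  )
}

#' Fill short sensor gaps by linear interpolation
#'
#' Training-set preprocessing: every maximal run of missing samples strictly
#' shorter than `max_gap_minutes` and bounded by observed values on both
#' sides is replaced by linear interpolation. Longer runs, and runs touching
#' either end of the series, are left untouched. Test data should never be
#' imputed; applying this only to the training split is the caller's
#' responsibility.
#'
#' @param series a [glucose_series()].
#' @param max_gap_minutes strict upper bound on the gap duration eligible for
#'   interpolation (default 30: a 30-minute, i.e. 6-sample, gap is NOT filled).
#' @return A [glucose_series()] with eligible gaps filled.
#' @export
fill_short_gaps <- function(series, max_gap_minutes = 30) {
  step <- sampling_minutes(series)
  max_run <- ceiling(max_gap_minutes / step) - 1L # strictly shorter than the bound
  if (max_run < 1L || !anyNA(series$glucose)) {
    return(series)
  }
  filled <- as.numeric(zoo::na.approx(series$glucose, maxgap = max_run, na.rm = FALSE))
  glucose_series(series$time, filled, step)
}

#' Split a CGM series and its event log into train and test periods
#'
#' The test set is the final `test_days` calendar days present on the grid;
#' everything earlier is training data. Events are partitioned by timestamp
#' with the same cutoff, so no sample or event belongs to both parts.
#'
#' @param series a [glucose_series()].
#' @param events an event log tibble (see [read_events_csv()]); may be `NULL`.
#' @param test_days number of trailing calendar days reserved for testing.
#' @return A list with elements `train` and `test`, each a list holding
#'   `series` and `events`.
#' @export
split_train_test <- function(series, events = NULL, test_days = 10) {
  assert_scalar_count(test_days, "test_days", min = 0L)
  dates <- as.Date(series$time, tz = "UTC")
  u <- sort(unique(dates))
  if (length(u) <= test_days) {
    abort(sprintf("Series spans %d day(s); need more than test_days = %d.",
                  length(u), test_days))
  }
  if (test_days == 0) {
    cutoff <- as.Date(Inf)
  } else {
    cutoff <- u[length(u) - test_days + 1L]
  }
  in_test <- dates >= cutoff
  step <- sampling_minutes(series)
  split_events <- function(keep_test) {
    if (is.null(events)) return(NULL)
    ev_dates <- as.Date(events$time, tz = "UTC")
    events[if (keep_test) ev_dates >= cutoff else ev_dates < cutoff, , drop = FALSE]
  }
  test_series <- if (any(in_test)) {
    as_glucose_series(series[in_test, ], step)
  } else {
    NULL
  }
  list(
    train = list(series = as_glucose_series(series[!in_test, ], step),
                 events = split_events(FALSE)),
    test = list(series = test_series, events = split_events(TRUE))
  )
}

#' @rdname glucose_series
#' @param object,x a `glucose_series`.
#' @param ... unused.
#' @method glance glucose_series
#' @export
glance.glucose_series <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_slots = nrow(x),
      start = min(x$time),
      end = max(x$time),
      sampling_minutes = sampling_minutes(x)
    ),
    glycemic_summary(x)
  )
}
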