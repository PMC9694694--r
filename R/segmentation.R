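#' Segment a CGM trace into fixed-length postprandial periods
#'
#' Each meal anchors one candidate postprandial period (PP): the window
#' starts at the meal's grid slot and runs for `window_samples` slots (4 h at
#' 5-minute sampling) or until the next meal's slot, whichever comes first.
#' Windows cut short by an early next meal (or by the end of the recording)
#' are padded with `NA` to the fixed length, so every PP has exactly
#' `window_samples` entries — the fixed length is what later lets PPs be
#' concatenated into a series with an enforced seasonal period. The
#' `n_presamples` grid slots immediately before the meal are kept alongside
#' the window for model initialisation.
#'
#' A candidate whose *observed region* (the part of the window before
#' padding starts) contains more than `max_missing` missing samples — 1.5 h
#' of data at the default — is discarded: too little data to say which
#' response shape it was. Structural `NA` padding does not count towards
#' this limit. A meal whose own grid slot is missing still anchors a PP.
#'
#' @param series a [glucose_series()].
#' @param events an [event_log()] (only meal rows are used).
#' @param window_samples PP window length in slots (default 48 = 4 h).
#' @param n_presamples pre-meal slots kept for initialisation (default 5).
#' @param max_missing discard threshold on missing samples in the observed
#'   region (default 18 = 1.5 h).
#' @param include_hypo_treatments whether hypoglycemia-treatment meals anchor
#'   PPs (default `TRUE`; see [meal_events()]).
#' @return A tibble of class `pp_set`, one row per retained PP, with columns
#'   `meal_index`, `meal_time`, `slot` (1-based grid slot of the meal in
#'   `series`), list-columns `window` (length `window_samples`) and
#'   `presamples` (length `n_presamples`), `observed_length`,
#'   `n_missing`, `start`, `end`.
#' @export
segment_postprandial <- function(series, events,
                                 window_samples = 48, n_presamples = 5,
                                 max_missing = 18,
                                 include_hypo_treatments = TRUE) {
  meals <- meal_events(events, include_hypo_treatments)
  step_sec <- sampling_minutes(series) * 60
  n <- nrow(series)
  if (nrow(meals) == 0) {
    return(empty_pp_set(window_samples, n_presamples))
  }
  slot <- snap_to_grid(meals$time, series$time[1], step_sec) + 1L
  inside <- slot >= 1L & slot <= n
  if (any(!inside)) {
    warn(sprintf("Skipping %d meal(s) outside the CGM series span.", sum(!inside)))
  }
  meals <- meals[inside, , drop = FALSE]
  slot <- slot[inside]
  next_slot <- c(slot[-1], Inf)

  rows <- purrr::map(seq_along(slot), function(j) {
    s <- slot[j]
    obs_len <- min(window_samples, next_slot[j] - s, n - s + 1L)
    if (obs_len < 1L) {
      warn(sprintf("Skipping meal %d: no grid slot before the next meal.", j))
      return(NULL)
    }
    window <- rep(NA_real_, window_samples)
    window[seq_len(obs_len)] <- series$glucose[s:(s + obs_len - 1L)]
    n_missing <- sum(is.na(window[seq_len(obs_len)]))
    if (n_missing > max_missing) {
      inform(sprintf("Discarding PP at meal %d: %d missing samples in the observed region (limit %d).",
                     j, n_missing, max_missing))
      return(NULL)
    }
    pre <- rep(NA_real_, n_presamples)
    pre_idx <- (s - n_presamples):(s - 1L)
    ok <- pre_idx >= 1L
    pre[ok] <- series$glucose[pre_idx[ok]]
    tibble::tibble(
      meal_index = j,
      meal_time = meals$time[j],
      slot = as.integer(s),
      window = list(window),
      presamples = list(pre),
      observed_length = as.integer(obs_len),
      n_missing = as.integer(n_missing),
      start = series$time[s],
      end = series$time[s + obs_len - 1L]
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    return(empty_pp_set(window_samples, n_presamples))
  }
  new_pp_set(out, window_samples, n_presamples)
}

new_pp_set <- function(df, window_samples, n_presamples) {
  attr(df, "window_samples") <- window_samples
  attr(df, "n_presamples") <- n_presamples
  class(df) <- unique(c("pp_set", class(df)))
  df
}

empty_pp_set <- function(window_samples, n_presamples) {
  new_pp_set(
    tibble::tibble(
      meal_index = integer(), meal_time = as.POSIXct(character(), tz = "UTC"),
      slot = integer(), window = list(), presamples = list(),
      observed_length = integer(), n_missing = integer(),
      start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC")
    ),
    window_samples, n_presamples
  )
}

# N x window_samples matrix of PP windows (rows = PPs), NA = missing.
pp_matrix <- function(pps) {
  do.call(rbind, pps$window)
}

#' @export
print.pp_set <- function(x, ...) {
  cat(sprintf("<pp_set> %d postprandial periods (window %d slots + %d presamples)\n",
              nrow(x), attr(x, "window_samples"), attr(x, "n_presamples")))
  NextMethod()
}

#' Long-format view of a postprandial period set
#'
#' @param x a `pp_set` from [segment_postprandial()].
#' @param ... unused.
#' @return A tibble with one row per (PP, slot): `meal_index`,
#'   `slot_in_window` (1-based), `glucose`, `padded`.
#' @method tidy pp_set
#' @export
tidy.pp_set <- function(x, ...) {
  w <- attr(x, "window_samples")
  tidyr::unnest_longer(
    dplyr::mutate(
      tibble::tibble(meal_index = x$meal_index,
                     observed_length = x$observed_length,
                     glucose = x$window),
      slot_in_window = list(seq_len(w))
    ),
    c("glucose", "slot_in_window")
  ) |>
    dplyr::mutate(padded = .data$slot_in_window > .data$observed_length) |>
    dplyr::select("meal_index", "slot_in_window", "glucose", "padded")
}
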