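#' Configuration for the synthetic CGM subject generator
#'
#' The generator emulates the structure of free-living CGM studies: weeks of
#' 5-minute sampling, a circadian baseline, meal-triggered glucose
#' excursions drawn from a small set of archetype response shapes,
#' autocorrelated sensor noise, and sensor-dropout gaps (defaults tuned so
#' that realised missingness, time-in-range and the coefficient of variation
#' land in the ranges typical of real open-loop cohorts: ~12% missing,
#' TIR 40-90%, CV 20-45%). It makes no claim of physiological fidelity —
#' no insulin-glucose dynamics, no exercise — it only reproduces the
#' statistical features the forecasting pipeline consumes.
#'
#' @param days monitoring length in days.
#' @param archetypes tibble with one row per meal-response archetype and
#'   columns `peak` (excursion height, mg/dL), `tp_min` (time to peak,
#'   minutes), `decay_min` (tail time constant, minutes).
#' @param baseline_mean fasting baseline, mg/dL.
#' @param circadian_amplitude amplitude of the sinusoidal circadian term,
#'   mg/dL.
#' @param noise_sd marginal standard deviation of the AR(1) sensor noise,
#'   mg/dL.
#' @param noise_ar1 lag-1 autocorrelation of the sensor noise, in (-1, 1).
#' @param missing_rate target fraction of missing samples, in [0, 1).
#' @param gap_length_mean mean dropout-gap length, samples.
#' @param meal_times daily meal schedule, "HH:MM" strings.
#' @param meal_jitter_sd_min meal-time jitter standard deviation, minutes.
#' @param cho_per_peak logged carbohydrate grams per mg/dL of archetype peak
#'   (meal size scales with the response it triggers).
#' @param basal_rate constant basal insulin rate, IU/h.
#' @param sampling_minutes grid spacing.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(days = 56,
                       archetypes = default_archetypes(),
                       baseline_mean = 115, circadian_amplitude = 10,
                       noise_sd = 6, noise_ar1 = 0.6,
                       missing_rate = 0.12, gap_length_mean = 4,
                       meal_times = c("07:30", "12:30", "19:00"),
                       meal_jitter_sd_min = 20,
                       cho_per_peak = 0.5, basal_rate = 1,
                       sampling_minutes = 5, seed = 1L) {
  if (nrow(archetypes) < 1) abort("Need at least one archetype.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (abs(noise_ar1) >= 1) abort("`noise_ar1` must be in (-1, 1).")
  structure(
    list(days = days, archetypes = archetypes, baseline_mean = baseline_mean,
         circadian_amplitude = circadian_amplitude, noise_sd = noise_sd,
         noise_ar1 = noise_ar1, missing_rate = missing_rate,
         gap_length_mean = gap_length_mean, meal_times = meal_times,
         meal_jitter_sd_min = meal_jitter_sd_min, cho_per_peak = cho_per_peak,
         basal_rate = basal_rate, sampling_minutes = sampling_minutes,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_archetypes <- function() {
  archetype_library()[1:3, ]
}

# Library of qualitatively distinct postprandial response kinetics. The
# shapes are deliberately non-collinear in profile space (they differ in
# kinetics, not just amplitude): a set where one curve is an average of two
# others is not "K distinct archetypes" but a 1-D continuum, and no
# clustering method can be expected to resolve it.
archetype_library <- function() {
  tibble::tibble(
    label = c("fast_sharp", "large_mixed", "slow_flat",
              "late_sharp", "small_snack", "fast_then_slow"),
    peak = c(90, 160, 80, 140, 60, 120),
    tp_min = c(30, 60, 100, 90, 45, 40),
    decay_min = c(35, 80, 140, 60, 50, 110)
  )
}

# Gamma-density-shaped meal response: unimodal rise/decay with mode at
# `tp_min` and exponential tail time constant `decay_min`, scaled to `peak`.
archetype_curve <- function(t_min, peak, tp_min, decay_min) {
  a <- tp_min / decay_min
  r <- ifelse(t_min <= 0, 0,
              (t_min / tp_min)^a * exp(-(t_min - tp_min) / decay_min))
  peak * r
}

#' Generate one synthetic CGM subject
#'
#' Glucose = circadian baseline + sum of archetype meal responses + AR(1)
#' sensor noise, clipped to the device range [40, 400] mg/dL. Each meal is
#' assigned an archetype uniformly at random; logged carbohydrates are
#' proportional to the archetype peak, each meal gets an insulin bolus
#' (1 IU / 10 g), and a constant basal rate is recorded. Sensor dropouts are
#' an on/off renewal process with geometric gap lengths calibrated so the
#' stationary missing fraction equals `missing_rate`; a gap that would
#' swallow a meal's own slot is undone there with probability
#' 1 - missing_rate (meals are self-reported, independent of the sensor).
#' Fully reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `series` (a [glucose_series()]), `events` (an
#'   [event_log()]), and `labels` (tibble: `meal_index`, `time`,
#'   `archetype` — the ground-truth response class of each meal).
#' @export
generate_subject <- function(config) {
  with_seed(config$seed, generate_subject_impl(config))
}

generate_subject_impl <- function(cfg) {
  step <- cfg$sampling_minutes
  n <- cfg$days * 24L * 60L %/% step
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  time <- t0 + (seq_len(n) - 1L) * step * 60
  hours <- as.numeric(time - t0, units = "hours")

  # circadian term with late-afternoon acrophase
  glucose <- cfg$baseline_mean +
    cfg$circadian_amplitude * sin(2 * pi * (hours - 11) / 24)

  # meal schedule with jitter
  sched_min <- purrr::map_dbl(cfg$meal_times, function(s) {
    hm <- as.numeric(strsplit(s, ":")[[1]])
    hm[1] * 60 + hm[2]
  })
  meal_min <- as.numeric(sapply(seq_len(cfg$days) - 1L, function(d) {
    d * 1440 + sched_min + stats::rnorm(length(sched_min), 0, cfg$meal_jitter_sd_min)
  }))
  meal_slot <- pmax(1L, pmin(n, round(meal_min / step) + 1L))
  meal_slot <- sort(meal_slot)
  K <- nrow(cfg$archetypes)
  archetype <- sample.int(K, length(meal_slot), replace = TRUE)

  # superimpose meal responses (evaluated out to 6 h)
  resp_len <- 6L * 60L %/% step
  t_resp <- (seq_len(resp_len) - 1L) * step
  for (j in seq_along(meal_slot)) {
    a <- cfg$archetypes[archetype[j], ]
    idx <- meal_slot[j]:min(n, meal_slot[j] + resp_len - 1L)
    glucose[idx] <- glucose[idx] +
      archetype_curve(t_resp[seq_along(idx)], a$peak, a$tp_min, a$decay_min)
  }

  # AR(1) sensor noise with marginal sd noise_sd
  if (cfg$noise_sd > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$noise_ar1^2)
    e <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                  cfg$noise_ar1, method = "recursive"))
    glucose <- glucose + e
  }
  glucose <- pmin(400, pmax(40, glucose))

  # sensor dropout: on/off renewal process with stationary missing fraction
  missing <- rep(FALSE, n)
  if (cfg$missing_rate > 0) {
    L <- cfg$gap_length_mean
    q <- cfg$missing_rate / ((1 - cfg$missing_rate) * L)
    i <- 1L
    while (i <= n) {
      if (stats::runif(1) < q) {
        len <- stats::rgeom(1, 1 / L) + 1L
        missing[i:min(n, i + len - 1L)] <- TRUE
        i <- i + len
      } else {
        i <- i + 1L
      }
    }
    hit <- which(missing[meal_slot])
    if (length(hit) > 0) {
      keep <- stats::runif(length(hit)) < (1 - cfg$missing_rate)
      missing[meal_slot[hit[keep]]] <- FALSE
    }
  }
  glucose[missing] <- NA_real_

  series <- glucose_series(time, glucose, step)
  meal_time <- time[meal_slot]
  cho <- round(cfg$cho_per_peak * cfg$archetypes$peak[archetype])
  events <- event_log(
    time = c(meal_time, meal_time, time[1]),
    kind = rep(c("meal", "bolus", "basal"), c(length(meal_time), length(meal_time), 1L)),
    amount = c(cho, round(cho / 10, 1), cfg$basal_rate),
    label = c(rep("meal", length(meal_time)), rep(NA_character_, length(meal_time) + 1L))
  )
  labels <- tibble::tibble(meal_index = seq_along(meal_slot),
                           time = meal_time, archetype = archetype)
  list(series = series, events = events, labels = labels)
}

#' Generate a labelled set of postprandial windows for clustering tests
#'
#' Draws `n_per_cluster` windows per archetype on the 48-slot grid (archetype
#' curve on a flat baseline plus i.i.d. Gaussian noise) and optionally
#' truncates a fraction of them with `NA` padding, emulating windows cut
#' short by an early next meal.
#'
#' @param K number of archetypes (2..nrow(archetypes)).
#' @param n_per_cluster windows per archetype.
#' @param noise_sd i.i.d. noise standard deviation, mg/dL.
#' @param seed integer seed.
#' @param truncate_frac fraction of windows to pad (observed length drawn
#'   uniformly in 24..47 slots).
#' @param archetypes archetype table as in [sim_config()].
#' @param baseline flat baseline, mg/dL.
#' @param window_samples window length in slots.
#' @param sampling_minutes grid spacing.
#' @return List with `X` (N x `window_samples` matrix, `NA` = padding) and
#'   `labels` (integer archetype of each row).
#' @export
generate_pp_set <- function(K = 3, n_per_cluster = 20, noise_sd = 5,
                            seed = 1L, truncate_frac = 0,
                            archetypes = NULL, baseline = 110,
                            window_samples = 48, sampling_minutes = 5) {
  if (K < 2) abort("`K` must be >= 2.")
  if (is.null(archetypes)) {
    lib <- archetype_library()
    if (K > nrow(lib)) {
      abort(sprintf("Built-in archetype library has %d shapes; supply `archetypes` for K = %d.",
                    nrow(lib), K))
    }
    archetypes <- lib[seq_len(K), ]
  }
  if (nrow(archetypes) < K) abort("`archetypes` must have at least K rows.")
  with_seed(seed, {
    t_min <- (seq_len(window_samples) - 1L) * sampling_minutes
    labels <- rep(seq_len(K), each = n_per_cluster)
    X <- do.call(rbind, purrr::map(labels, function(k) {
      a <- archetypes[k, ]
      baseline + archetype_curve(t_min, a$peak, a$tp_min, a$decay_min) +
        stats::rnorm(window_samples, 0, noise_sd)
    }))
    if (truncate_frac > 0) {
      n_trunc <- round(truncate_frac * nrow(X))
      rows <- sample.int(nrow(X), n_trunc)
      for (r in rows) {
        keep <- sample(24:(window_samples - 1L), 1)
        X[r, (keep + 1L):window_samples] <- NA_real_
      }
    }
    list(X = X, labels = labels)
  })
}
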