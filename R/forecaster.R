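#' Train a cluster-based seasonal ARIMA (C-SARIMA) forecaster
#'
#' The offline half of the method: (1) group the training postprandial
#' periods with partial-distance fuzzy C-means, selecting the cluster count
#' and fuzzifier by the Fukuyama-Sugeno index; (2) for each cluster,
#' concatenate its PPs (presamples + window) into an artificial series with
#' seasonal period S = presamples + window and identify a SARIMA model by
#' BIC grid search.
#'
#' @param pps a `pp_set` of training postprandial periods.
#' @param cluster_grid a [cluster_search_grid()].
#' @param model_grid a [sarima_grid()].
#' @param seed integer seed (clustering initialisation).
#' @return An object of class `csarima`: `cluster_set`, `models` (one
#'   `sarima_spec` per cluster), `s`, `window_samples`, `n_presamples`,
#'   `burn_in`, `seed`.
#' @export
train_csarima <- function(pps, cluster_grid = cluster_search_grid(),
                          model_grid = sarima_grid(), seed = 1L) {
  window_samples <- attr(pps, "window_samples") %||% 48L
  n_presamples <- attr(pps, "n_presamples") %||% 5L
  s <- window_samples + n_presamples
  cluster_set <- select_clustering(pps, cluster_grid, seed = seed)
  inform(sprintf("Selected %d clusters (m = %g, Fukuyama-Sugeno %.4g).",
                 cluster_set$n_clusters, cluster_set$fuzzifier, cluster_set$validity))
  histories <- vector("list", cluster_set$n_clusters)
  models <- purrr::map(seq_len(cluster_set$n_clusters), function(i) {
    series <- build_seasonal_series(pps, cluster_set, i)
    histories[[i]] <<- as.numeric(series)
    spec <- select_sarima(series, model_grid, s = s)
    inform(sprintf("Cluster %d: %d PPs, SARIMA(%s)(%s)[%d], BIC %.1f.",
                   i, attr(series, "n_pp"), paste(spec$order, collapse = ","),
                   paste(spec$seasonal_order, collapse = ","), s, spec$bic))
    spec
  })
  structure(
    list(cluster_set = cluster_set, models = models, histories = histories,
         s = s, window_samples = window_samples, n_presamples = n_presamples,
         burn_in = 3L, condition_seasons = 4L, seed = as.integer(seed)),
    class = "csarima"
  )
}

# Conditioning history for cluster i's local model at test time: the tail of
# that cluster's concatenated training series (whole seasons, so the seasonal
# phase stays aligned) followed by the in-progress season. Without the
# training tail the seasonal lags would have no data to reference and every
# local forecast would collapse to the model's constant mean.
local_history <- function(bundle, i, presamples, window_so_far) {
  tail_len <- (bundle$condition_seasons %||% 4L) * bundle$s
  hs <- bundle$histories
  h <- if (!is.null(hs) && length(hs) >= i) hs[[i]] %||% numeric(0) else numeric(0)
  c(tail(h, tail_len), presamples, window_so_far)
}

#' @export
print.csarima <- function(x, ...) {
  cat(sprintf("<csarima> %d local seasonal models (S = %d), fuzzifier %g\n",
              x$cluster_set$n_clusters, x$s, x$cluster_set$fuzzifier))
  invisible(x)
}

#' @rdname train_csarima
#' @param x a `csarima` bundle.
#' @param ... unused.
#' @method glance csarima
#' @export
glance.csarima <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$cluster_set$n_clusters,
    fuzzifier = x$cluster_set$fuzzifier,
    validity = x$cluster_set$validity,
    s = x$s, burn_in = x$burn_in, seed = x$seed
  )
}

validate_ph <- function(ph_minutes, sampling_minutes) {
  if (length(ph_minutes) > 0 &&
      (any(ph_minutes <= 0) || any(ph_minutes %% sampling_minutes != 0))) {
    abort(sprintf("Every prediction horizon must be a positive multiple of the %g-minute sampling interval.",
                  sampling_minutes))
  }
  as.integer(ph_minutes / sampling_minutes)
}

#' Open the real-time forecasting loop at a mealtime
#'
#' Initialises the per-meal forecast state: the 5 pre-meal samples seed every
#' local model's history, and no output is produced until the burn-in of 3
#' observed post-meal samples (15 min of data) has accumulated.
#'
#' @param presamples the pre-meal CGM samples (`NA` = missing).
#' @param bundle a fitted [train_csarima()] object.
#' @param ph_minutes prediction horizons in minutes (default 30/45/60/75).
#' @param sampling_minutes grid spacing (default 5).
#' @return A `pp_forecast_state` object; advance it with [step_pp()].
#' @export
start_pp <- function(presamples, bundle, ph_minutes = c(30, 45, 60, 75),
                     sampling_minutes = 5) {
  ph_steps <- validate_ph(ph_minutes, sampling_minutes)
  structure(
    list(presamples = as.numeric(presamples), window = numeric(0),
         n_observed = 0L, ph_minutes = as.integer(ph_minutes),
         ph_steps = ph_steps, bundle = bundle, weights = NULL,
         local_predictions = NULL, output = NULL),
    class = "pp_forecast_state"
  )
}

#' Advance the forecasting loop by one CGM sample
#'
#' Appends the new sample (possibly missing) to the in-progress window.
#' Once at least 3 post-meal samples have been *observed*, each new observed
#' sample refreshes the cluster weights from the observed prefix; a missing
#' sample freezes the weights and leaves a missing slot in the conditioning
#' history. The emitted forecast at each horizon is the weight-averaged
#' combination of the per-cluster SARIMA predictions, each conditioned on
#' (tail of that cluster's concatenated training series, presamples,
#' post-meal prefix) — the training tail is what gives the seasonal lags
#' something to reference, so each local model predicts its cluster's
#' response shape. State never carries over between test PPs.
#'
#' @param state a `pp_forecast_state`.
#' @param new_sample glucose value in mg/dL, or `NA`.
#' @return The updated state; `state$output` holds the latest per-horizon
#'   predictions (named by horizon minutes) or is `NULL` before burn-in.
#' @export
step_pp <- function(state, new_sample) {
  bundle <- state$bundle
  if (length(state$window) >= bundle$window_samples) {
    abort("This postprandial window is closed (48 slots already recorded).")
  }
  state$window <- c(state$window, as.numeric(new_sample))
  if (!is.na(new_sample)) {
    state$n_observed <- state$n_observed + 1L
    prefix <- rep(NA_real_, bundle$window_samples)
    prefix[seq_along(state$window)] <- state$window
    state$weights <- score_membership(prefix, bundle$cluster_set)
  }
  if (state$n_observed >= bundle$burn_in && length(state$ph_steps) > 0) {
    h <- max(state$ph_steps)
    local <- do.call(rbind, purrr::map(seq_along(bundle$models), function(i) {
      history <- local_history(bundle, i, state$presamples, state$window)
      sarima_forecast(bundle$models[[i]], history, h)[state$ph_steps]
    }))
    state$local_predictions <- local
    state$output <- setNames(as.numeric(state$weights %*% local),
                             as.character(state$ph_minutes))
  } else {
    state$local_predictions <- NULL
    state$output <- NULL
  }
  state
}

# Shared pairing arithmetic: the forecast made at post-meal slot t for
# horizon step s targets window slot t + s; a pair is evaluable only when
# that slot is inside the fixed window and its glucose was observed.
pp_target_at <- function(window, t, steps) {
  idx <- t + steps
  out <- rep(NA_real_, length(steps))
  ok <- idx <= length(window)
  out[ok] <- window[idx[ok]]
  out
}

#' Replay the real-time loop over a recorded postprandial period
#'
#' Feeds a PP's observed sequence through [start_pp()]/[step_pp()] exactly as
#' the online procedure would have seen it, and tabulates every prediction
#' against its target. Targets falling outside the 48-slot window or on
#' missing slots are `NA` (excluded from evaluation pairs downstream).
#'
#' @param pp one row of a `pp_set` (a list with `window`, `presamples`,
#'   `meal_index`, `observed_length`).
#' @param bundle a [train_csarima()] fit.
#' @param ph_minutes prediction horizons in minutes.
#' @param sampling_minutes grid spacing.
#' @return Tibble with columns `meal_index`, `slot` (forecast origin, post-
#'   meal samples so far), `ph_minutes`, `y_hat`, `target`.
#' @export
predict_pp <- function(pp, bundle, ph_minutes = c(30, 45, 60, 75),
                       sampling_minutes = 5) {
  state <- start_pp(pp$presamples, bundle, ph_minutes, sampling_minutes)
  if (length(state$ph_steps) == 0) {
    return(tibble::tibble(meal_index = integer(), slot = integer(),
                          ph_minutes = integer(), y_hat = double(),
                          target = double()))
  }
  window <- pp$window
  rows <- vector("list", pp$observed_length)
  for (t in seq_len(pp$observed_length)) {
    state <- step_pp(state, window[t])
    if (!is.null(state$output)) {
      rows[[t]] <- tibble::tibble(
        meal_index = pp$meal_index, slot = t,
        ph_minutes = state$ph_minutes,
        y_hat = as.numeric(state$output),
        target = pp_target_at(window, t, state$ph_steps)
      )
    }
  }
  dplyr::bind_rows(purrr::compact(rows))
}

#' Predict every postprandial period of a test set
#'
#' @param object a `csarima` bundle.
#' @param pps a `pp_set` of test PPs.
#' @param ph_minutes prediction horizons in minutes.
#' @param sampling_minutes grid spacing.
#' @param ... unused.
#' @return Long tibble (`meal_index`, `slot`, `ph_minutes`, `y_hat`,
#'   `target`) with a `method = "C-SARIMA"` column.
#' @export
predict.csarima <- function(object, pps, ph_minutes = c(30, 45, 60, 75),
                            sampling_minutes = 5, ...) {
  out <- purrr::map(seq_len(nrow(pps)), function(j) {
    predict_pp(list(window = pps$window[[j]], presamples = pps$presamples[[j]],
                    meal_index = pps$meal_index[j],
                    observed_length = pps$observed_length[j]),
               object, ph_minutes, sampling_minutes)
  })
  dplyr::mutate(dplyr::bind_rows(out), method = "C-SARIMA")
}

#' Serialise / restore a C-SARIMA model bundle as JSON
#'
#' The bundle holds the fitted cluster set (prototypes, fuzzifier) and one
#' SARIMA specification per cluster — everything the online forecasting loop
#' needs.
#'
#' @param bundle a `csarima` object.
#' @param path output JSON path.
#' @return `path` (write) or the restored `csarima` object (read).
#' @export
write_model_bundle <- function(bundle, path) {
  jsonlite::write_json(
    list(
      s = bundle$s, window_samples = bundle$window_samples,
      n_presamples = bundle$n_presamples, burn_in = bundle$burn_in,
      condition_seasons = bundle$condition_seasons %||% 4L,
      histories = bundle$histories %||% list(),
      seed = bundle$seed,
      cluster_set = list(
        n_clusters = bundle$cluster_set$n_clusters,
        fuzzifier = bundle$cluster_set$fuzzifier,
        validity = bundle$cluster_set$validity,
        prototypes = bundle$cluster_set$prototypes
      ),
      models = purrr::map(bundle$models, function(m) {
        list(order = m$order, seasonal_order = m$seasonal_order, s = m$s,
             coef = as.list(m$coef), sigma2 = m$sigma2, loglik = m$loglik,
             bic = m$bic, n_obs = m$n_obs, include_mean = m$include_mean,
             converged = m$converged)
      })
    ),
    path, digits = NA, auto_unbox = TRUE, na = "null"
  )
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- structure(
    list(n_clusters = as.integer(j$cluster_set$n_clusters),
         fuzzifier = j$cluster_set$fuzzifier,
         prototypes = as.matrix(j$cluster_set$prototypes),
         memberships = NULL, objective = NA_real_,
         objective_history = numeric(0), validity = j$cluster_set$validity,
         n_iter = NA_integer_, seed = as.integer(j$seed)),
    class = "pdsfcm"
  )
  models <- purrr::map(seq_len(cs$n_clusters), function(i) {
    m <- if (is.data.frame(j$models)) as.list(j$models[i, ]) else j$models[[i]]
    new_sarima_spec(
      order = as.integer(unlist(m$order)),
      seasonal_order = as.integer(unlist(m$seasonal_order)),
      s = as.integer(m$s), coef = unlist(m$coef), sigma2 = m$sigma2,
      loglik = m$loglik, bic = m$bic, n_obs = m$n_obs,
      include_mean = isTRUE(m$include_mean), converged = isTRUE(m$converged)
    )
  })
  histories <- j$histories
  if (is.matrix(histories)) {
    histories <- lapply(seq_len(nrow(histories)), function(i) histories[i, ])
  }
  structure(
    list(cluster_set = cs, models = models,
         histories = lapply(histories, as.numeric), s = as.integer(j$s),
         window_samples = as.integer(j$window_samples),
         n_presamples = as.integer(j$n_presamples),
         burn_in = as.integer(j$burn_in),
         condition_seasons = as.integer(j$condition_seasons %||% 4L),
         seed = as.integer(j$seed)),
    class = "csarima"
  )
}
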