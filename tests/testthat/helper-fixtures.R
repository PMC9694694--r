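# Shared fixtures, all built in code.

t0 <- function(h = 8, m = 0) {
  as.POSIXct(sprintf("2023-01-01 %02d:%02d:00", h, m), tz = "UTC")
}

# Uniform 5-min series starting 08:00 from a glucose vector (NA = missing).
make_series <- function(values, start = t0()) {
  glucose_series(start + (seq_along(values) - 1L) * 300, values)
}

# pp_set wrapper around a matrix of windows (rows = PPs), flat presamples.
pp_set_from_matrix <- function(X, presamples = rep(110, 5)) {
  n <- nrow(X)
  df <- tibble::tibble(
    meal_index = seq_len(n),
    meal_time = t0() + seq_len(n) * 3600,
    slot = seq_len(n),
    window = lapply(seq_len(n), function(i) as.numeric(X[i, ])),
    presamples = rep(list(as.numeric(presamples)), n),
    observed_length = vapply(seq_len(n), function(i) {
      obs <- which(!is.na(X[i, ]))
      if (length(obs) == 0) ncol(X) else max(obs)
    }, integer(1)),
    n_missing = 0L,
    start = t0() + seq_len(n) * 3600,
    end = t0() + seq_len(n) * 3600
  )
  csarima:::new_pp_set(df, ncol(X), length(presamples))
}

# Hand-built AR(1) model spec: y_t = mean + phi * (y_{t-1} - mean) + e.
ar1_spec <- function(phi, mean = 0, sigma2 = 1, s = 53) {
  csarima:::new_sarima_spec(
    order = c(1L, 0L, 0L), seasonal_order = c(0L, 0L, 0L), s = s,
    coef = c(ar1 = phi, intercept = mean), sigma2 = sigma2,
    loglik = NA_real_, bic = NA_real_, n_obs = NA_integer_,
    include_mean = TRUE, converged = TRUE
  )
}

# Random-walk spec: (0,1,0), forecasts repeat the last observed value.
rw_spec <- function(sigma2 = 1, s = 53) {
  csarima:::new_sarima_spec(
    order = c(0L, 1L, 0L), seasonal_order = c(0L, 0L, 0L), s = s,
    coef = setNames(numeric(0), character(0)), sigma2 = sigma2,
    loglik = NA_real_, bic = NA_real_, n_obs = NA_integer_,
    include_mean = FALSE, converged = TRUE
  )
}

# Minimal C-SARIMA bundle from explicit prototypes and model specs.
manual_bundle <- function(prototypes, models, fuzzifier = 2,
                          window_samples = 48L, n_presamples = 5L) {
  cs <- structure(
    list(n_clusters = nrow(prototypes), fuzzifier = fuzzifier,
         prototypes = prototypes, memberships = NULL, objective = NA_real_,
         objective_history = numeric(0), validity = NA_real_,
         n_iter = NA_integer_, seed = 1L),
    class = "pdsfcm"
  )
  structure(
    list(cluster_set = cs, models = models,
         s = window_samples + n_presamples,
         window_samples = window_samples, n_presamples = n_presamples,
         burn_in = 3L, seed = 1L),
    class = "csarima"
  )
}

# Best-permutation agreement between a hard clustering and true labels.
label_accuracy <- function(assigned, truth) {
  k <- max(assigned, truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[assigned] == truth))
  }
  best
}
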