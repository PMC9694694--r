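#' Concatenate a cluster's postprandial periods into a seasonal series
#'
#' For every PP hard-assigned (argmax membership) to `cluster_index`, emits
#' its 5 presamples followed by its 48-slot window — missing markers
#' preserved — and concatenates the blocks in chronological order. Because
#' every block has the same length, the artificial series has an enforced
#' seasonal period S = presamples + window (53 by default): the repeated
#' meal-response shape becomes a seasonality that a SARIMA model can capture
#' even though raw CGM traces have none.
#'
#' @param pps a `pp_set` from [segment_postprandial()].
#' @param cluster_set a `pdsfcm` fit on the same PPs.
#' @param cluster_index which cluster's series to build.
#' @return Numeric vector (`NA` = missing) of length S * n_assigned, with
#'   attributes `period` and `n_pp`.
#' @export
build_seasonal_series <- function(pps, cluster_set, cluster_index) {
  labels <- hard_assignment(cluster_set)
  if (length(labels) != nrow(pps)) {
    abort("`cluster_set` was not fitted on these postprandial periods.")
  }
  idx <- which(labels == cluster_index)
  if (length(idx) == 0) {
    abort(sprintf("No postprandial period is hard-assigned to cluster %d.", cluster_index))
  }
  idx <- idx[order(pps$meal_time[idx])]
  blocks <- purrr::map(idx, function(j) c(pps$presamples[[j]], pps$window[[j]]))
  out <- unlist(blocks)
  attr(out, "period") <- length(blocks[[1]])
  attr(out, "n_pp") <- length(idx)
  out
}

#' Fit a seasonal ARIMA model by exact maximum likelihood
#'
#' Thin wrapper around the state-space (Kalman filter) estimator in
#' [stats::arima()]: missing entries are treated as unobserved in the
#' filtering recursion, never imputed. A constant term is included for
#' undifferenced models (d = D = 0). A fit is flagged as non-converged —
#' rather than raising an error, so that grid searches can simply skip it —
#' when the optimiser fails, reports a non-zero convergence code, or returns
#' a non-invertible moving-average polynomial.
#'
#' The reported BIC follows the convention k * ln(n_eff) - 2 * loglik with
#' k = number of estimated coefficients + 1 (the innovation variance) and
#' n_eff the number of observations entering the likelihood after
#' differencing.
#'
#' @param series numeric vector (`NA` = missing).
#' @param order non-seasonal (p, d, q).
#' @param seasonal_order seasonal (P, D, Q).
#' @param s seasonal period in samples (default 53 = 5 presamples + 48
#'   window slots).
#' @return An object of class `sarima_spec`: orders, named coefficient
#'   vector, `sigma2`, `loglik`, `bic`, `n_obs`, `include_mean`,
#'   `converged`.
#' @export
fit_sarima <- function(series, order, seasonal_order = c(0, 0, 0), s = 53) {
  series <- as.numeric(series)
  order <- as.integer(order)
  seasonal_order <- as.integer(seasonal_order)
  if (length(order) != 3 || length(seasonal_order) != 3 ||
      any(order < 0) || any(seasonal_order < 0)) {
    abort("`order` and `seasonal_order` must be three non-negative integers each.")
  }
  n_min <- if (sum(seasonal_order) > 0) 3L * s else 10L
  if (length(series) < n_min) {
    abort(sprintf("Series of length %d is too short for this model (need >= %d).",
                  length(series), n_min))
  }
  include_mean <- order[2] == 0 && seasonal_order[2] == 0
  fit <- tryCatch(
    stats::arima(series, order = order,
                 seasonal = list(order = seasonal_order, period = s),
                 include.mean = include_mean, method = "ML"),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(failed_sarima_spec(order, seasonal_order, s, include_mean,
                              conditionMessage(fit)))
  }
  converged <- isTRUE(fit$code == 0) && sarima_roots_ok(fit)
  n_eff <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1
  se <- tryCatch(sqrt(pmax(diag(fit$var.coef), 0)), error = function(e) NULL)
  spec <- new_sarima_spec(
    order = order, seasonal_order = seasonal_order, s = s,
    coef = stats::coef(fit), sigma2 = fit$sigma2, loglik = fit$loglik,
    bic = k * log(n_eff) - 2 * fit$loglik, n_obs = n_eff,
    include_mean = include_mean, converged = converged
  )
  spec$se <- se
  spec
}

new_sarima_spec <- function(order, seasonal_order, s, coef, sigma2, loglik,
                            bic, n_obs, include_mean, converged,
                            message = NULL) {
  structure(
    list(order = order, seasonal_order = seasonal_order, s = s, coef = coef,
         sigma2 = sigma2, loglik = loglik, bic = bic, n_obs = n_obs,
         include_mean = include_mean, converged = converged,
         message = message),
    class = "sarima_spec"
  )
}

failed_sarima_spec <- function(order, seasonal_order, s, include_mean, msg) {
  new_sarima_spec(order, seasonal_order, s, coef = numeric(0),
                  sigma2 = NA_real_, loglik = NA_real_, bic = Inf,
                  n_obs = NA_integer_, include_mean = include_mean,
                  converged = FALSE, message = msg)
}

# Stationarity of the AR polynomials is enforced by the estimator's
# parameterisation; non-invertible MA polynomials (roots strictly inside the
# unit circle) are treated as identification failures.
sarima_roots_ok <- function(fit) {
  co <- stats::coef(fit)
  pick <- function(prefix) co[grep(paste0("^", prefix, "[0-9]+$"), names(co))]
  ok <- function(theta, lower) {
    if (length(theta) == 0) return(TRUE)
    all(Mod(polyroot(c(1, theta))) >= lower)
  }
  ok(pick("ma"), 1 - 1e-8) && ok(pick("sma"), 1 - 1e-8)
}

#' @export
print.sarima_spec <- function(x, ...) {
  cat(sprintf("<sarima_spec> (%s)(%s)[%d]%s  BIC %.2f%s\n",
              paste(x$order, collapse = ","),
              paste(x$seasonal_order, collapse = ","), x$s,
              if (x$include_mean) " + mean" else "",
              x$bic, if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @rdname fit_sarima
#' @param x a `sarima_spec`.
#' @param ... unused.
#' @method tidy sarima_spec
#' @export
tidy.sarima_spec <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = as.numeric(x$coef))
}

#' @rdname fit_sarima
#' @method glance sarima_spec
#' @export
glance.sarima_spec <- function(x, ...) {
  tibble::tibble(
    p = x$order[1], d = x$order[2], q = x$order[3],
    P = x$seasonal_order[1], D = x$seasonal_order[2], Q = x$seasonal_order[3],
    s = x$s, sigma2 = x$sigma2, loglik = x$loglik, bic = x$bic,
    n_obs = x$n_obs, converged = x$converged
  )
}

#' SARIMA identification grid
#'
#' Default order ranges for the per-cluster model identification:
#' p in 1..4, q in 0..4, d in {0,1}, P in 1..3, Q in 0..3, D in {0,1}.
#'
#' @param p,q,d,P,Q,D integer vectors of candidate orders.
#' @return A list of class `sarima_grid`.
#' @export
sarima_grid <- function(p = 1:4, q = 0:4, d = 0:1, P = 1:3, Q = 0:3, D = 0:1) {
  structure(list(p = p, q = q, d = d, P = P, Q = Q, D = D),
            class = "sarima_grid")
}

#' Select SARIMA orders by exhaustive BIC grid search
#'
#' Fits every cell of the grid with [fit_sarima()] and returns the converged
#' fit with minimal BIC. Ties break toward the smallest total number of
#' coefficients, then lexicographically on (p, d, q, P, D, Q).
#'
#' @param series numeric vector (`NA` = missing).
#' @param grid a [sarima_grid()].
#' @param s seasonal period (default 53).
#' @return The winning `sarima_spec`, with the full search table attached as
#'   attribute `search`.
#' @export
select_sarima <- function(series, grid = sarima_grid(), s = 53) {
  cells <- expand.grid(p = grid$p, d = grid$d, q = grid$q,
                       P = grid$P, D = grid$D, Q = grid$Q)
  fits <- purrr::map(seq_len(nrow(cells)), function(k) {
    fit_sarima(series, order = c(cells$p[k], cells$d[k], cells$q[k]),
               seasonal_order = c(cells$P[k], cells$D[k], cells$Q[k]), s = s)
  })
  search <- dplyr::bind_rows(purrr::map(fits, glance))
  conv <- which(search$converged)
  if (length(conv) == 0) {
    abort("No SARIMA grid cell converged on this series.")
  }
  n_par <- with(search, p + q + P + Q)
  ord <- conv[order(search$bic[conv], n_par[conv],
                    search$p[conv], search$d[conv], search$q[conv],
                    search$P[conv], search$D[conv], search$Q[conv])]
  best <- fits[[ord[1]]]
  attr(best, "search") <- search
  best
}

#' Forecast from a fitted SARIMA given an arbitrary history
#'
#' Conditions the model's state-space representation on the observed entries
#' of `history` (missing entries are skipped by the Kalman filter, never
#' imputed) and returns the 1..h step-ahead predictions. All coefficients
#' are held fixed at their fitted values; only the filter state is run over
#' the new history, so repeated calls are deterministic.
#'
#' With an empty (or all-missing) history — or a history too short for the
#' model's differencing — the unconditional forecast is returned instead
#' (the fitted constant for undifferenced models, otherwise the last
#' observed value), flagged via attribute `unconditional`.
#'
#' @param model a converged `sarima_spec`.
#' @param history numeric vector (`NA` = missing) ending at the forecast
#'   origin t.
#' @param h number of steps ahead.
#' @return Numeric vector of h predictions, mg/dL.
#' @export
sarima_forecast <- function(model, history, h) {
  assert_scalar_count(h, "h", min = 1L)
  if (!model$converged) abort("Refusing to forecast from a non-converged model.")
  history <- as.numeric(history)
  fallback <- function() {
    level <- if (model$include_mean && "intercept" %in% names(model$coef)) {
      unname(model$coef["intercept"])
    } else if (any(!is.na(history))) {
      history[max(which(!is.na(history)))]
    } else {
      NA_real_
    }
    structure(rep(level, h), unconditional = TRUE)
  }
  if (length(history) == 0 || all(is.na(history))) {
    return(fallback())
  }
  # warnings here are expected: with every coefficient fixed the optimiser
  # has nothing to do, and short histories make arima's internals chatty
  refit <- tryCatch(
    suppressWarnings(
      stats::arima(history, order = model$order,
                   seasonal = list(order = model$seasonal_order, period = model$s),
                   include.mean = model$include_mean, fixed = model$coef,
                   transform.pars = FALSE, method = "ML")
    ),
    error = function(e) e
  )
  if (inherits(refit, "error")) {
    return(fallback())
  }
  as.numeric(stats::predict(refit, n.ahead = h)$pred)
}
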