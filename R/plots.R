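#' Plot a CGM trace
#'
#' Glucose over time with the 70-180 mg/dL target band; meal events, if
#' supplied, are marked as vertical ticks.
#'
#' @param object a [glucose_series()].
#' @param events optional [event_log()] whose meals are marked.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot glucose_series
#' @export
autoplot.glucose_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$glucose)) +
    ggplot2::annotate("rect", xmin = min(object$time), xmax = max(object$time),
                      ymin = 70, ymax = 180, alpha = 0.08, fill = "forestgreen") +
    ggplot2::geom_line(na.rm = TRUE, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Glucose (mg/dL)") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    meals <- meal_events(events)
    if (nrow(meals) > 0) {
      p <- p + ggplot2::geom_vline(data = meals,
                                   ggplot2::aes(xintercept = .data$time),
                                   colour = "firebrick", alpha = 0.4,
                                   linetype = "dotted")
    }
  }
  p
}

#' Plot the fitted cluster prototypes
#'
#' One curve per cluster prototype over the postprandial window.
#'
#' @param object a `pdsfcm` fit.
#' @param sampling_minutes grid spacing for the time axis.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pdsfcm
#' @export
autoplot.pdsfcm <- function(object, sampling_minutes = 5, ...) {
  df <- tidy(object)
  df$minutes <- (df$slot_in_window - 1) * sampling_minutes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minutes, y = .data$glucose,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Minutes after meal", y = "Glucose (mg/dL)",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-PP RMSE distributions by method and horizon
#'
#' @param object a `csarima_eval` from [evaluate_predictions()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot csarima_eval
#' @export
autoplot.csarima_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_pp,
                  ggplot2::aes(x = factor(.data$ph_minutes), y = .data$rmse,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Prediction horizon (min)", y = "Per-PP RMSE (mg/dL)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one predicted postprandial period against its target
#'
#' Shows, for a single PP and horizon, the realised window and the sequence
#' of PH-ahead predictions placed at their target times.
#'
#' @param predictions a long prediction tibble from [predict.csarima()] or
#'   [predict_pp_benchmark()].
#' @param meal_index which PP to show.
#' @param ph which horizon (minutes).
#' @param sampling_minutes grid spacing.
#' @return A ggplot object.
#' @export
plot_pp_forecast <- function(predictions, meal_index, ph = 30,
                             sampling_minutes = 5) {
  df <- dplyr::filter(predictions, .data$meal_index == !!meal_index,
                      .data$ph_minutes == !!ph)
  if (nrow(df) == 0) abort("No predictions for that PP / horizon.")
  df$target_minutes <- (df$slot - 1) * sampling_minutes + ph
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_minutes)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$target, linetype = "observed"),
                       na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_hat, colour = .data$method),
                       na.rm = TRUE) +
    ggplot2::labs(x = "Minutes after meal", y = "Glucose (mg/dL)",
                  colour = NULL, linetype = NULL,
                  title = sprintf("PP %d, PH = %d min", meal_index, ph)) +
    ggplot2::theme_minimal()
}
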