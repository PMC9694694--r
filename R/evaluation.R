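#' Root-mean-squared error of one predicted postprandial period
#'
#' RMSE = sqrt(mean((target - prediction)^2)) over the available
#' prediction/target pairs; rows where either side is missing are dropped
#' first. Returns `NA` (with a message) when no valid pair remains, so the
#' caller can exclude the PP from aggregation rather than zero-fill it.
#'
#' @param target,prediction numeric vectors (mg/dL), equal length.
#' @return RMSE in mg/dL, or `NA_real_` if no valid pair exists.
#' @export
rmse_pp <- function(target, prediction) {
  if (length(target) != length(prediction)) {
    abort("`target` and `prediction` must have equal length.")
  }
  ok <- !is.na(target) & !is.na(prediction)
  if (!any(ok)) {
    inform("No valid prediction/target pair; RMSE undefined for this PP.")
    return(NA_real_)
  }
  sqrt(mean((target[ok] - prediction[ok])^2))
}

#' Aggregate per-PP prediction errors into cohort summaries
#'
#' Mirrors the reporting convention of the glucose-forecasting literature:
#' RMSE per (subject, PP, horizon), then the per-subject median over that
#' subject's PPs, then the cohort median and [25th, 75th] percentiles
#' (linear interpolation between order statistics) over subject medians, per
#' horizon and method. PPs with no valid pair at a horizon are excluded.
#'
#' @param predictions long tibble with columns `method`, `ph_minutes`,
#'   `meal_index`, `y_hat`, `target`, and optionally `subject` (defaulting
#'   to a single subject).
#' @return An object of class `csarima_eval`: list of tibbles `per_pp`,
#'   `per_subject`, `cohort`.
#' @export
evaluate_predictions <- function(predictions) {
  if (!"subject" %in% names(predictions)) {
    predictions <- dplyr::mutate(predictions, subject = 1L)
  }
  per_pp <- predictions |>
    dplyr::group_by(.data$subject, .data$method, .data$meal_index, .data$ph_minutes) |>
    dplyr::summarise(rmse = rmse_pp(.data$target, .data$y_hat),
                     n_pairs = sum(!is.na(.data$target) & !is.na(.data$y_hat)),
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$rmse))
  per_subject <- per_pp |>
    dplyr::group_by(.data$subject, .data$method, .data$ph_minutes) |>
    dplyr::summarise(median_rmse = stats::median(.data$rmse),
                     n_pp = dplyr::n(), .groups = "drop")
  cohort <- per_subject |>
    dplyr::group_by(.data$method, .data$ph_minutes) |>
    dplyr::summarise(
      median = stats::median(.data$median_rmse),
      q1 = stats::quantile(.data$median_rmse, 0.25, names = FALSE),
      q3 = stats::quantile(.data$median_rmse, 0.75, names = FALSE),
      n_subjects = dplyr::n(), .groups = "drop"
    )
  structure(list(per_pp = per_pp, per_subject = per_subject, cohort = cohort),
            class = "csarima_eval")
}

#' @export
print.csarima_eval <- function(x, ...) {
  cat("<csarima_eval> cohort median [IQR] RMSE (mg/dL):\n")
  print(x$cohort)
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x a `csarima_eval`.
#' @param ... unused.
#' @method tidy csarima_eval
#' @export
tidy.csarima_eval <- function(x, ...) x$per_pp

#' @rdname evaluate_predictions
#' @method glance csarima_eval
#' @export
glance.csarima_eval <- function(x, ...) x$cohort

#' Normality-gated paired comparison of two methods
#'
#' Tests whether two methods' paired accuracy values differ: a Shapiro-Wilk
#' test on the paired differences (at `alpha`) gates the choice between a
#' paired t-test (normality accepted) and a Wilcoxon signed-rank test
#' (normality rejected). The natural pairing unit is the per-subject median
#' RMSE, but any paired vectors work. All-zero differences return p = 1 by
#' convention.
#'
#' @param a,b equal-length paired numeric vectors (length >= 3).
#' @param alpha significance level (default 0.05), used both for the
#'   normality gate and the final call.
#' @return One-row tibble: `test`, `p_value`, `significant`.
#' @export
compare_methods <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired (equal length).")
  if (length(a) < 3) abort("Need at least 3 pairs.")
  d <- a - b
  if (all(d == 0)) {
    return(tibble::tibble(test = "none (identical)", p_value = 1, significant = FALSE))
  }
  normal <- tryCatch(stats::shapiro.test(d)$p.value >= alpha,
                     error = function(e) FALSE)
  if (normal) {
    p <- stats::t.test(a, b, paired = TRUE)$p.value
    test <- "paired t-test"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    test <- "Wilcoxon signed-rank"
  }
  tibble::tibble(test = test, p_value = p, significant = p < alpha)
}

#' Pairwise method comparisons from an evaluation result
#'
#' Runs [compare_methods()] on per-subject median RMSEs for every pair of
#' methods at every horizon.
#'
#' @param eval_result a [evaluate_predictions()] result.
#' @param alpha significance level.
#' @return Tibble: `method_a`, `method_b`, `ph_minutes`, `test`, `p_value`,
#'   `significant`.
#' @export
compare_all_methods <- function(eval_result, alpha = 0.05) {
  ps <- eval_result$per_subject
  methods <- sort(unique(ps$method))
  if (length(methods) < 2) {
    return(tibble::tibble(method_a = character(), method_b = character(),
                          ph_minutes = integer(), test = character(),
                          p_value = double(), significant = logical()))
  }
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  grid <- tidyr::expand_grid(pair = pairs, ph = sort(unique(ps$ph_minutes)))
  purrr::pmap_dfr(grid, function(pair, ph) {
    wide <- ps |>
      dplyr::filter(.data$ph_minutes == ph, .data$method %in% pair) |>
      dplyr::select("subject", "method", "median_rmse") |>
      tidyr::pivot_wider(names_from = "method", values_from = "median_rmse") |>
      dplyr::filter(stats::complete.cases(dplyr::pick(dplyr::everything())))
    if (nrow(wide) < 3) {
      return(tibble::tibble(method_a = pair[1], method_b = pair[2],
                            ph_minutes = ph, test = "skipped (n < 3)",
                            p_value = NA_real_, significant = NA))
    }
    res <- compare_methods(wide[[pair[1]]], wide[[pair[2]]], alpha)
    tibble::tibble(method_a = pair[1], method_b = pair[2], ph_minutes = ph,
                   test = res$test, p_value = res$p_value,
                   significant = res$significant)
  })
}

#' Write an evaluation report (long CSV + JSON summary)
#'
#' @param eval_result a [evaluate_predictions()] result.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return Invisibly, the list of written paths.
#' @export
write_evaluation <- function(eval_result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(eval_result$per_pp, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_subject = eval_result$per_subject, cohort = eval_result$cohort),
      json_path, digits = NA, auto_unbox = TRUE
    )
  }
  invisible(list(csv = csv_path, json = json_path))
}
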