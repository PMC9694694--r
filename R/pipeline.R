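#' Pipeline configuration
#'
#' Collects every tunable constant of the method in one validated list:
#' the 5-minute sampling grid, the 48-slot (4 h) postprandial window, the 5
#' presamples, the implied seasonal period 53, the 3-sample burn-in, the
#' 18-sample missing-data discard rule, the 30-minute gap-fill bound, the
#' 10-day test split, the 30/45/60/75-minute horizons, and the three
#' identification grids. `seasonality` must equal
#' `pp_window_samples + presamples` — the concatenation construction makes
#' any other value inconsistent.
#'
#' @param sampling_minutes CGM grid spacing, minutes.
#' @param pp_window_samples postprandial window length, slots.
#' @param presamples pre-meal slots kept for initialisation.
#' @param seasonality seasonal period of the concatenated series, slots.
#' @param burn_in_samples observed post-meal samples before the first output.
#' @param max_missing_pp discard threshold for missing samples in a PP.
#' @param gap_fill_max_minutes strict upper bound for training gap interpolation.
#' @param test_days trailing calendar days held out for testing.
#' @param ph_minutes prediction horizons, minutes.
#' @param include_hypo_treatments whether rescue-carb meals anchor PPs.
#' @param cluster_grid a [cluster_search_grid()].
#' @param model_grid a [sarima_grid()].
#' @param benchmark_grids list with optional entries `arima` and `arimax`,
#'   each a [benchmark_grid()].
#' @param seed integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sampling_minutes = 5, pp_window_samples = 48,
                            presamples = 5, seasonality = 53,
                            burn_in_samples = 3, max_missing_pp = 18,
                            gap_fill_max_minutes = 30, test_days = 10,
                            ph_minutes = c(30, 45, 60, 75),
                            include_hypo_treatments = TRUE,
                            cluster_grid = cluster_search_grid(),
                            model_grid = sarima_grid(),
                            benchmark_grids = list(arima = benchmark_grid()),
                            seed = 1L) {
  if (seasonality != pp_window_samples + presamples) {
    abort(sprintf("`seasonality` (%d) must equal pp_window_samples + presamples (%d + %d).",
                  seasonality, pp_window_samples, presamples))
  }
  if (burn_in_samples < 1) abort("`burn_in_samples` must be >= 1.")
  structure(
    list(sampling_minutes = sampling_minutes,
         pp_window_samples = pp_window_samples, presamples = presamples,
         seasonality = seasonality, burn_in_samples = burn_in_samples,
         max_missing_pp = max_missing_pp,
         gap_fill_max_minutes = gap_fill_max_minutes, test_days = test_days,
         ph_minutes = ph_minutes,
         include_hypo_treatments = include_hypo_treatments,
         cluster_grid = cluster_grid, model_grid = model_grid,
         benchmark_grids = benchmark_grids, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys mirror the [pipeline_config()] arguments; the grids accept
#' nested keys (`cluster_grid: {nC_range: [2, 8], m_grid: [1.6, 2.0]}`,
#' `model_grid: {p: [1, 2], ...}`, `benchmark_grids: {arima: {ar: ...}}`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("cluster_grid", "model_grid", "benchmark_grids")))]
  if (!is.null(y$cluster_grid)) {
    args$cluster_grid <- do.call(cluster_search_grid, y$cluster_grid)
  }
  if (!is.null(y$model_grid)) {
    args$model_grid <- do.call(sarima_grid, y$model_grid)
  }
  if (!is.null(y$benchmark_grids)) {
    args$benchmark_grids <- purrr::map(y$benchmark_grids,
                                       function(g) do.call(benchmark_grid, g))
  }
  do.call(pipeline_config, args)
}

#' Run the full forecasting pipeline on one subject
#'
#' Executes segment -> cluster -> identify -> predict -> evaluate: fills
#' short training gaps, splits off the trailing test days, segments both
#' parts into postprandial periods, trains the C-SARIMA bundle on the
#' training PPs, optionally fits the requested benchmarks on the training
#' series, predicts every test PP with every method, and aggregates the
#' errors. Each stage reports its counts. Given the same inputs, config and
#' seed the result is identical.
#'
#' @param series a [glucose_series()] (the full recording).
#' @param events an [event_log()].
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, artifacts (model bundle JSON, predictions
#'   CSV, evaluation CSV/JSON) are written there.
#' @return List with `bundle`, `benchmarks`, `predictions` (long tibble,
#'   all methods), `evaluation` (a `csarima_eval`), `comparisons`, and
#'   `counts` (per-stage bookkeeping).
#' @export
run_pipeline <- function(series, events, config = pipeline_config(),
                         out_dir = NULL) {
  split <- split_train_test(series, events, config$test_days)
  train_series <- fill_short_gaps(split$train$series, config$gap_fill_max_minutes)
  inform(sprintf("Split: %d train slots, %d test slots.",
                 nrow(train_series), nrow(split$test$series)))
  seg <- function(s, ev) {
    segment_postprandial(s, ev,
                         window_samples = config$pp_window_samples,
                         n_presamples = config$presamples,
                         max_missing = config$max_missing_pp,
                         include_hypo_treatments = config$include_hypo_treatments)
  }
  train_pps <- seg(train_series, split$train$events)
  test_pps <- seg(split$test$series, split$test$events)
  inform(sprintf("Segmented %d training and %d test postprandial periods.",
                 nrow(train_pps), nrow(test_pps)))

  bundle <- train_csarima(train_pps, config$cluster_grid, config$model_grid,
                          seed = config$seed)
  predictions <- predict(bundle, test_pps, config$ph_minutes,
                         config$sampling_minutes)

  benchmarks <- list()
  for (kind in names(config$benchmark_grids)) {
    exog <- if (kind == "arimax") {
      build_exog_signals(split$train$events, train_series)
    } else {
      NULL
    }
    fit <- fit_benchmark(train_series, exog, config$benchmark_grids[[kind]])
    inform(sprintf("Benchmark %s: orders (%s), x = %d.", fit$kind,
                   paste(fit$order, collapse = ","), fit$x_lag))
    benchmarks[[kind]] <- fit
    predictions <- dplyr::bind_rows(
      predictions,
      predict_pp_benchmark(fit, split$test$series, test_pps,
                           events = split$test$events,
                           ph_minutes = config$ph_minutes,
                           burn_in = config$burn_in_samples)
    )
  }

  evaluation <- evaluate_predictions(predictions)
  comparisons <- compare_all_methods(evaluation)
  counts <- tibble::tibble(
    stage = c("train_slots", "test_slots", "train_pps", "test_pps", "clusters"),
    n = c(nrow(train_series), nrow(split$test$series), nrow(train_pps),
          nrow(test_pps), bundle$cluster_set$n_clusters)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model_bundle(bundle, file.path(out_dir, "model_bundle.json"))
    readr::write_csv(predictions, file.path(out_dir, "predictions.csv"), na = "")
    write_evaluation(evaluation, file.path(out_dir, "evaluation.csv"),
                     file.path(out_dir, "evaluation.json"))
  }
  list(bundle = bundle, benchmarks = benchmarks, predictions = predictions,
       evaluation = evaluation, comparisons = comparisons, counts = counts)
}
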