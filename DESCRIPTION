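Package: csarima
Title: Cluster-Based Seasonal ARIMA Forecasting of Postprandial Glucose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Short-to-mid-term blood-glucose forecasting from continuous
    glucose monitoring (CGM) data using cluster-based seasonal ARIMA
    (C-SARIMA) local models. CGM traces are segmented into fixed-length
    postprandial periods, grouped by partial-distance fuzzy C-means with
    automatic selection of the cluster count and fuzzifier via the
    Fukuyama-Sugeno validity index, and one seasonal ARIMA model is
    identified per cluster on an artificially concatenated seasonal
    series. Real-time forecasts are membership-weighted combinations of
    the local model predictions. Includes individualized ARIMA/ARIMAX
    benchmarks, RMSE-based evaluation with paired statistical
    comparisons, and a seeded synthetic CGM generator for fully
    reproducible end-to-end experiments without access-restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml,
    zoo
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
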