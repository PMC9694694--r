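# csarima

Short-to-mid-term blood-glucose forecasting from continuous glucose
monitoring (CGM) data with **cluster-based seasonal ARIMA (C-SARIMA) local
models**, for researchers working on glucose prediction in type 1 diabetes
and for anyone who needs a fully reproducible, meal-anchored forecasting
pipeline on 5-minute CGM traces.

## The method

Raw CGM traces have no exploitable periodicity, but postprandial responses
do repeat in a few characteristic shapes. C-SARIMA manufactures a
seasonality out of that repetition:

1. **Segment.** Every meal anchors a postprandial period (PP): 48 five-minute
   slots (4 h), truncated at the next meal and NA-padded back to length 48,
   plus the 5 pre-meal samples. PPs with more than 18 missing samples (1.5 h)
   in their observed region are discarded.
2. **Cluster.** PPs are grouped by partial-distance fuzzy C-means,

   d²(x, v) = (D / I) · Σₖ∈obs (xₖ − vₖ)²,  D = 48,

   which handles sensor dropouts and structural padding alike. The cluster
   count nC and fuzzifier m are selected by exhaustive grid search on the
   Fukuyama–Sugeno validity index.
3. **Identify.** Per cluster, the PPs are concatenated into an artificial
   series with seasonal period S = 53 (= 5 presamples + 48 window slots) and
   a SARIMA model

   φₚ(z⁻¹) Φₚ(z⁻ˢ) ∇ₛᴰ ∇ᵈ ω(t) = θ_q(z⁻¹) Θ_Q(z⁻ˢ) ε(t),  y(t) = α + ω(t)

   is chosen by BIC over a grid of orders (exact ML via the Kalman filter;
   missing entries skipped, never imputed).
4. **Forecast in real time.** At mealtime the loop waits for 3 observed
   samples (15 min), then at every new sample recomputes fuzzy membership
   weights from the observed prefix and emits

   ŷ(t+PH|t) = Σᵢ wᵢ · ŷᵢ(t+PH|t)

   for PH ∈ {30, 45, 60, 75} min — a convex combination of the per-cluster
   SARIMA forecasts.

The package also provides the standard comparators (individualized ARIMA on
CGM only; ARIMAX fed by logged carbohydrate and insulin impulses), RMSE
evaluation per predicted PP with median [IQR] aggregation and
normality-gated paired tests (Shapiro–Wilk gating paired t vs Wilcoxon
signed-rank), readers for a plain CSV layout and for the OhioT1DM XML
layout, and a seeded synthetic CGM generator — the clinical datasets this
method is usually evaluated on are access-restricted, so every experiment
here runs on synthetic subjects.

## Worked example

```r
library(csarima)

sub <- generate_subject(sim_config(days = 16, seed = 2))
glycemic_summary(sub$series)
#> # A tibble: 1 × 5
#>      cv   tbr   tir   tar missing_pct
#>   <dbl> <dbl> <dbl> <dbl>       <dbl>
#> 1  30.6     0  73.3  26.7        14.8

cfg <- pipeline_config(
  test_days = 6,
  cluster_grid = cluster_search_grid(nC_range = 2:4, m_grid = c(1.6, 2.0), restarts = 3),
  model_grid = sarima_grid(p = 1:2, q = 0, d = 0, P = 1, Q = 0, D = 0),
  benchmark_grids = list(arima = benchmark_grid(ar = 1:3, ma = 0:1, i = 0:1, x = 1)),
  seed = 2
)
res <- run_pipeline(sub$series, sub$events, cfg)
#> Segmented 30 training and 16 test postprandial periods.
#> Selected 4 clusters (m = 1.6, Fukuyama-Sugeno -1.679e+06).
#> Cluster 1: 8 PPs, SARIMA(1,0,0)(1,0,0)[53], BIC 2801.5.
#> ...
#> Benchmark ARIMA: orders (2,0,1), x = 0.

res$evaluation
#> <csarima_eval> cohort median [IQR] RMSE (mg/dL):
#> # A tibble: 8 × 6
#>   method   ph_minutes median    q1    q3 n_subjects
#>   <chr>         <int>  <dbl> <dbl> <dbl>      <int>
#> 1 ARIMA            30   13.7  13.7  13.7          1
#> 2 ARIMA            45   16.3  16.3  16.3          1
#> 3 ARIMA            60   20.6  20.6  20.6          1
#> 4 ARIMA            75   24.1  24.1  24.1          1
#> 5 C-SARIMA         30   10.3  10.3  10.3          1
#> 6 C-SARIMA         45   11.4  11.4  11.4          1
#> 7 C-SARIMA         60   12.5  12.5  12.5          1
#> 8 C-SARIMA         75   13.6  13.6  13.6          1
```

Reading the table: each entry is the median over this subject's test PPs of
the per-PP RMSE between ŷ(t+PH|t) and the realised CGM value, in mg/dL. On
this synthetic subject the meal-anchored C-SARIMA degrades slowly with the
horizon (10.3 → 13.6 mg/dL), while the individualized ARIMA — which knows
nothing about meals — degrades fast (13.7 → 24.1 mg/dL); the gap at PH ≥ 60
is the method's selling point. `autoplot(res$evaluation)` draws the per-PP
RMSE distributions, `autoplot(res$bundle$cluster_set)` the fitted prototype
curves.

A thin command-line driver over the same functions ships in
`inst/cli/csarima.R` (subcommands `simulate`, `segment`, `cluster`,
`identify`, `predict`, `benchmark`, `evaluate`, `run`).

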