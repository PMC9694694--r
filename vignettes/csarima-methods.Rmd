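---
title: "Cluster-based seasonal ARIMA forecasting of postprandial glucose: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based seasonal ARIMA forecasting of postprandial glucose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csarima)
```

## The problem

Continuous glucose monitoring (CGM) sensors report interstitial glucose every
5 minutes. For people with type 1 diabetes, predictions 30-75 minutes ahead
enable preventive action against hypo- and hyperglycemia. Raw CGM traces have
no exploitable periodicity, but the glucose response *after a meal* is highly
structured: it rises, peaks, and decays in one of a few characteristic ways.
C-SARIMA (cluster-based seasonal ARIMA) turns that structure into an
artificial seasonality:

1. **Segmentation.** Each meal anchors a postprandial period (PP): the 48
   grid slots (4 h) from the meal, truncated at the next meal and NA-padded
   back to 48, plus the 5 pre-meal samples kept for state initialisation.
   PPs with more than 18 missing samples (1.5 h) in their observed region are
   discarded.
2. **Clustering.** PPs are grouped by fuzzy C-means using a partial distance
   that handles both sensor dropouts and structural NA padding. The number of
   clusters and the fuzzifier are selected by exhaustive grid search on the
   Fukuyama-Sugeno validity index.
3. **Identification.** Per cluster, the PPs (presamples + window) are
   concatenated into a series with enforced seasonal period S = 53, and a
   SARIMA model is selected by BIC over a grid of orders.
4. **Real-time forecasting.** At each meal the loop waits for 3 observed
   post-meal samples, then, at every new sample, recomputes fuzzy membership
   weights from the observed prefix and emits the weight-averaged combination
   of the per-cluster SARIMA forecasts at each prediction horizon.

The package also implements the standard comparators (individualized ARIMA
from CGM only, and ARIMAX fed by logged carbohydrates and insulin), the
RMSE-based evaluation with normality-gated paired tests, and a seeded
synthetic CGM generator, because the clinical datasets this class of method
is usually evaluated on are access-restricted.

## Models

**Partial-distance fuzzy C-means.** For profiles $x_j \in \mathbb{R}^{48}$
with missing entries and complete prototypes $v_i$, the squared partial
distance is

$$d^2(x_j, v_i) = \frac{D}{I_j} \sum_{k \,\text{observed}} (x_{jk} - v_{ik})^2,$$

with $D = 48$ and $I_j$ the number of observed coordinates — the rescaling
makes distances comparable across PPs with different padding. Memberships
$w_{ij} \in [0,1]$ (rows summing to 1) minimise
$\sum_{i}\sum_{j} w_{ij}^m d^2(x_j, v_i)$ by alternating

$$v_{ik} = \frac{\sum_j w_{ij}^m \, x_{jk} \,[k \in \mathrm{obs}(j)]}{\sum_j w_{ij}^m \,[k \in \mathrm{obs}(j)]},
\qquad
w_{ij} = \left[ \sum_{c=1}^{n_C} \left( \frac{d^2(x_j, v_i)}{d^2(x_j, v_c)} \right)^{\frac{1}{m-1}} \right]^{-1}.$$

**Fukuyama-Sugeno index.** Cluster count $n_C$ and fuzzifier $m$ are chosen
to minimise

$$\mathrm{FS} = \sum_i \sum_j w_{ij}^m \left( d^2(x_j, v_i) - \lVert v_i - \bar v \rVert^2 \right),$$

where $\bar v$ is the grand prototype (the total-membership-weighted mean of
the data under the same observed-coordinate convention as the centroids) and
the separation term uses the plain Euclidean distance, since prototypes are
complete by construction.

**Seasonal models.** Writing $y(t) = \alpha + \omega(t)$, each cluster's
concatenated series is modelled as

$$\phi_p(z^{-1})\, \Phi_P(z^{-S})\, \nabla_S^D \nabla^d\, \omega(t) = \theta_q(z^{-1})\, \Theta_Q(z^{-S})\, \epsilon(t),$$

with $S = 53$. Estimation is exact maximum likelihood through the state-space
form (`stats::arima`); missing entries are skipped by the Kalman filter,
never imputed. Orders are selected by BIC
($k \ln n_\mathrm{eff} - 2 \ell$, $k$ counting coefficients plus the
innovation variance) over the grid $p \in 1..4$, $q \in 0..4$, $d \in
\{0,1\}$, $P \in 1..3$, $Q \in 0..3$, $D \in \{0,1\}$ by default.

**Prediction.** The output at horizon PH is
$\hat y(t+\mathrm{PH}|t) = \sum_i w_i \, \hat y_i(t+\mathrm{PH}|t)$, a convex
combination of the local forecasts.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sampling_minutes` | 5 | CGM grid spacing (device native rate) |
| `pp_window_samples` | 48 | PP length: 4 h of 5-min slots |
| `presamples` | 5 | pre-meal samples initialising each local model |
| `seasonality` | 53 | enforced period; must equal 48 + 5 |
| `max_missing_pp` | 18 | discard bound: 1.5 h of missing data |
| `gap_fill_max_minutes` | 30 | strict bound for training-gap interpolation |
| `burn_in_samples` | 3 | observed samples (15 min) before the first output |
| `test_days` | 10 | trailing calendar days held out |
| `ph_minutes` | 30/45/60/75 | prediction horizons |
| fuzzifier grid | 1.2-3.0 step 0.2 | `m = 1` is the singular crisp limit, so the grid starts just above it |
| cluster grid | 2-30 | candidate cluster counts |

## Design choices in the open places

- **What is clustered.** Distances use the 48-sample post-meal window only;
  the 5 presamples initialise the seasonal models but carry no information
  about the response *shape* that clustering should isolate.
- **What counts toward the 18-missing discard.** Only missing samples in the
  observed region. Structural NA padding from an early next meal is not
  missing data; counting it would discard every PP shorter than 30 slots and
  contradict the padding construction.
- **Hard assignment for concatenation.** Argmax membership, ties to the
  lowest index, blocks in chronological order (preserving slow drift). The
  alternative — fuzzy pooling of PPs into several clusters' series — would
  blur exactly the per-cluster homogeneity the seasonal models rely on.
- **Conditioning of the local forecasts.** Each cluster model's Kalman state
  is run over the tail of that cluster's concatenated *training* series
  (whole seasons, keeping the phase aligned) before the current presamples
  and prefix are appended. This is what lets the seasonal lag-S terms
  reference the typical response of the cluster; conditioned on the 8-50
  samples of the current meal alone, a stationary SARIMA would revert to its
  constant mean and every local model would predict a flat line. Four
  seasons of tail are retained (geometrically decaying memory makes longer
  tails numerically irrelevant); state never carries over between test PPs.
- **Zero-distance memberships.** A profile coinciding with one or more
  prototypes gets membership 1/|Z| on the zero-distance set — the continuous
  limit of the update rule.
- **Burn-in counts observed samples.** A missing slot during burn-in extends
  the wait; after burn-in it freezes the weights and leaves a missing slot
  in the conditioning history (no test-time imputation, ever).
- **Evaluation pairing.** A forecast made at post-meal slot $t$ for horizon
  step $s$ is paired with window slot $t+s$; pairs exist only inside the
  48-slot window and where the target was observed. Benchmarks emit
  predictions at exactly the same slots (after the same burn-in), so all
  methods are scored on identical pairs by one shared implementation.
- **Benchmark inputs.** ARIMAX carbohydrate/insulin inputs are raw impulses
  (the full amount at the event's slot; basal as rate/12 per slot,
  piecewise-constant between rate changes) entering through distributed lags
  of order X applied to both inputs independently. Future exogenous values
  inside the horizon are taken from the log — meals are announced, which is
  precisely the information advantage ARIMAX is meant to represent.
- **Cohort order selection.** Benchmark orders are fixed across subjects at
  the argmin of the *summed* per-subject BIC, then coefficients are
  re-estimated per subject.
- **Statistics.** Shapiro-Wilk at 0.05 gates paired t-test vs Wilcoxon
  signed-rank; the pairing unit is the per-subject median RMSE; percentiles
  interpolate linearly between order statistics (R type 7).

## Numerical conventions

- FCM initialisation draws each membership row from a symmetric
  Dirichlet(1) with a seeded generator; 5 restarts, best final objective
  kept; convergence when the largest membership change drops below 1e-5 or
  after 200 sweeps. The alternating updates make the objective
  non-increasing, which the tests assert.
- During the validity grid search, cells whose smallest hard-assigned
  cluster holds fewer than 3 PPs are rejected: a seasonal model cannot be
  identified on one or two concatenated periods.
- SARIMA fits flag non-convergence (optimiser failure or a non-invertible
  moving-average polynomial) and are skipped by the grid search rather than
  crashing it; BIC ties break toward fewer coefficients, then
  lexicographically.
- Timestamps snap to the nearest grid slot, ties toward the earlier slot;
  duplicate slots keep the last record.
- "Gaps smaller than 30 min" is strict: a 6-sample (exactly 30 min) gap is
  not interpolated, and edge gaps never are.

## The synthetic generator

`generate_subject()` emulates the statistical features of free-living CGM
studies that the pipeline consumes: 5-minute sampling over weeks, a
sinusoidal circadian baseline, meal-triggered excursions drawn from a small
library of archetype response shapes, AR(1) sensor noise, device clipping to
40-400 mg/dL, and sensor-dropout gaps from an on/off renewal process with
geometric lengths calibrated so the stationary missing fraction equals the
configured rate (~10-18% in the emulated cohorts). Meal responses are
gamma-density-shaped (smooth, unimodal, with independent time-to-peak and
decay), and the archetype library is deliberately *non-collinear*: shapes
differ in kinetics, not just amplitude. A family in which one archetype is
an affine average of two others is a 1-D continuum, not a set of distinct
response classes, and no validity index can be expected to resolve it — an
early draft of the library had exactly that defect.

Defaults (baseline 115 mg/dL, circadian amplitude 10, noise 6 mg/dL with
lag-1 correlation 0.6, 12% missing, three jittered daily meals) put the
generated subjects at TIR ≈ 70%, CV ≈ 31%, comparable to real open-loop
cohorts.

What the generator does **not** emulate: insulin-glucose physiology (no
insulin action, no counter-regulation), exercise, sensor drift or
recalibration artifacts, meal-size misreporting, or circadian variation in
meal-response shape. Passing tests therefore demonstrate that the machinery
recovers structure *of the kind the method presumes*; they are not evidence
about any particular clinical dataset.

## Problem sizes used by the tests and the acceptance script

Unit tests run the clustering on 30-60 profiles and the seasonal estimators
on simulated series of 1,200-3,000 points with a scaled-down period S = 10 —
the algebra is identical at S = 53, only slower. The end-to-end experiment
uses one synthetic subject (16 days in the tests, 20 in the acceptance
script, last 6-8 days held out), a cluster grid of 2-5 candidate clusters
with fuzzifiers {1.6, 2.0(, 2.4)}, and per-cluster SARIMA grids restricted
to p ≤ 2, seasonal P = 1, d = D = Q = 0: the smallest configuration at which
the full pipeline — segmentation through paired evaluation — is exercised in
a few minutes. The production defaults (cluster counts to 30, the full order
grid, S = 53 everywhere) remain what the exported functions use unless
overridden.

## Known limitations

- The Fukuyama-Sugeno index decreases monotonically in the fuzzifier, so the
  joint (nC, m) grid search effectively selects the smallest m in the grid;
  the m-dimension of the search mostly matters through the membership
  softness of the final fit. The index is also known to favour splitting
  clusters that lie far from the grand mean when profiles are
  high-dimensional and noisy.
- With tens of PPs per subject (weeks of data), per-cluster series are short
  and the BIC search gravitates to small orders; the full published grid
  only becomes informative with months of data.
- The ARIMAX regression structure (impulse inputs through distributed lags)
  is the minimal reading of "timing and amount"; physiological
  insulin-action or carbohydrate-absorption kernels would be better inputs
  but are deliberately out of scope.
- Forecast quality hinges on the weights: early in a PP the observed prefix
  may fit several prototypes, and a wrong soft assignment propagates into
  the combined forecast. This is intrinsic to the method, visible in the
  synthetic experiments, and the reason the burn-in exists.
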