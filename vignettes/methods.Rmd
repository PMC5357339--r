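---
title: "Models and methods: presence-only suitability and risk-area change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: presence-only suitability and risk-area change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragrisk)
```

## The problem

Wind-pollinated invasive plants such as ragweeds are a public-health concern:
their pollen is strongly allergenic, and a warming climate is expected to push
climatically suitable habitat — and with it high pollen loads — poleward.
`ragrisk` implements the full analysis chain used in this kind of assessment:
clean aggregated occurrence records, derive a small set of ecophysiologically
motivated bioclimatic predictors, fit a presence-only maximum-entropy
suitability model, evaluate it, project it under future climate scenarios, and
quantify the change in "high allergy risk" (HAR) area — the part of a
projection region whose suitability reaches the top quartile of present-day
suitability.

Because the real inputs are gigabyte-scale downloads, the package ships a
synthetic-data module that emulates them with a known ground truth, so that
every stage is testable end to end and parameter recovery can be measured
rather than assumed.

## Occurrence cleaning

Three filters are applied in a fixed order, and a cleaning report reconciles
the counts exactly:

1. **Off-grid**: records outside the working extent or on nodata ("sea")
   cells are dropped — the analogue of discarding obviously erroneous
   coordinates.
2. **Elevation mismatch**: a record whose cited elevation differs from the
   gridded elevation of its cell by strictly more than 100 m (configurable)
   is dropped; "exceeded" is read as a strict inequality, so a 100 m
   difference is retained. Records with no cited elevation are kept — only
   records carrying precise locality metadata can fail this check.
3. **Per-cell deduplication**: one record per occupied grid cell, keeping the
   first in input order (deterministic and order-stable).

## Bioclimatic predictors

Three annual predictors summarize the monthly climate:

* **GDD** (growing degree days, °C·day): `sum_m max(0, tmean_m − 5) × days_m`.
  The 5 °C base with the monthly-mean approximation is the standard
  macroclimate convention; the exact formulation behind the original analysis
  is not public, so the derivation is isolated behind one function.
* **Tmin** (°C): the cellwise minimum over the twelve monthly minimum
  temperatures — absolute minimum temperature of the coldest month.
* **WBAL** (mm·yr⁻¹): annual precipitation minus Thornthwaite potential
  evapotranspiration. Thornthwaite PET needs only monthly mean temperature
  and day length (from latitude), which is why it was chosen over
  radiation-based formulations; WBAL is signed and goes strongly negative in
  warm, dry cells, matching the −1000…1000 mm range over which response
  curves are typically read.

## The maximum-entropy model

Given presences \(x_1,\dots,x_m\) and a background sample (all valid cells of
the training region up to 10,000, then a seeded uniform subsample — the
conventional default background size), the model is the Gibbs distribution
over background cells maximizing

\[
\frac1m \sum_i \sum_j \lambda_j f_j(x_i) \;-\; \ln Z(\lambda)
\;-\; \sum_j \beta_j |\lambda_j|,
\qquad Z(\lambda) = \sum_{x\in\mathrm{bg}} e^{\sum_j \lambda_j f_j(x)} .
\]

Features \(f_j\) are linear, quadratic, pairwise-product and hinge transforms
of the predictors, min–max scaled to [0,1] on the background; hinge knots sit
at background quantiles strictly inside each predictor's range, in both
directions. Out-of-range inputs are clamped into the training envelope (the
classical behaviour of the reference implementation); where clamping matters
is exactly what the MESS surface reports.

Penalties are \(\beta_j = \mathrm{rm}\cdot c_{\mathrm{class}}\cdot
\sigma_j/\sqrt m\), with \(\sigma_j\) the presence-sample standard deviation
of feature \(j\) and class constants 1.0 (linear/quadratic/product) and 0.5
(hinge) — a coarse, configurable stand-in for the tabulated sample-size
dependent defaults of the reference implementation. \(\beta_j\) is floored at
1e−8 purely so the objective stays coercive when a feature is constant across
presences.

The convex problem is solved by proximal gradient descent (FISTA with
backtracking line search and function-value restart), to a relative objective
tolerance of 1e−6 with a 10,000-iteration cap; failing to converge is an
error, not a silent result. On small instances the solver is tested against a
brute-force grid search of the same objective, and in the unpenalized limit
against the moment-matching stationarity condition
\(E_{\text{model}}[f_j] = \bar f_j^{\text{presence}}\).

Two outputs are exposed: the **raw** relative occurrence rate
\(e^{\sum\lambda f}/Z\) (summing to 1 over the background) and the bounded
**logistic** suitability \(e^H r \tau/(1-\tau) / (1 + e^H r \tau/(1-\tau))\)
with \(H\) the entropy of the fitted background distribution and prevalence
\(\tau = 0.5\) — the historical logistic output, chosen over cloglog to match
the software version this analysis style is built on; a featureless model
scores exactly 0.5 everywhere.

## Tuning, replication and evaluation

* **AICc tuning**: candidate feature-class sets {L, LQ, LQH, LQP, LQPH} ×
  regularization multipliers {0.5, 1, 2, 3, 4} (both configurable; the grid
  actually searched in the original analysis is unpublished). The raw output
  is standardized over all cells, the presence log-likelihood computed, and
  `AICc = 2k − 2lnL + 2k(k+1)/(m−k−1)` with `k` the nonzero-coefficient
  count; `k ≥ m−1` marks a candidate invalid (infinite AICc). Ties break
  deterministically: fewer `k`, lower rm, then candidate order.
* **Replicates**: 15 seeded random 75/25 presence splits by default — the
  replicate count matches the published convention, while the split scheme
  (random subsampling) is a documented choice since none was named. The map
  is the cellwise mean over replicates; AUC is computed per replicate on the
  held-out presences against the full background as pseudo-absences
  (rank-based, ties counted half) and summarized as median ± SD with the
  conventional strict bands (>0.7 useful, >0.8 good, >0.9 very good).
* **Jackknife importance**: per predictor, a model with only that predictor
  (its L/Q/H features) is fitted and its training gain
  \(\frac1m\sum_i \ln(N\,\mathrm{raw}(x_i))\) recorded; importances are the
  only-variable gains floored at zero and normalized to sum to 1, the
  convention under which a per-species importance column sums to 1.000.
  Without-variable gains are reported alongside but do not enter the
  normalization.
* **MESS**: per predictor, the percent-like similarity of each projection
  cell to the reference (training background) sample, negative exactly where
  the cell leaves the reference range; the surface is the per-cell minimum.
  The tie convention for the reference quantile (`f`, strict less-than with
  ties counted half) mirrors the AUC convention.

## Risk-area change

The HAR threshold is the 75th percentile of present-day suitability over the
projection region's valid cells (linear interpolation between order
statistics — a convention had to be fixed and is configurable). The threshold
is computed **once**, from the current map, and reused to reclassify every
scenario map; a cell is high-risk iff suitability ≥ threshold, so the break
value itself belongs to the top class. Areas are cell counts × cell area
(default 100 km² for a 10 km equal-area cell; configurable, since "10 km²"
grid-size statements in this literature are ambiguous between cell edge and
cell area). Both printed change conventions are reported explicitly, because
published analyses mix them: `percent_increase = (F−C)/C·100` and
`percent_of_current = F/C·100`.

## The synthetic world

The generator emulates the shape of the real inputs, not their geography:

* Climate: a deterministic north–south temperature gradient (≈12 °C at 32° N
  falling to ≈−10 °C at 60° N) plus seeded Gaussian noise smoothed by a
  fixed-width moving average, a sinusoidal seasonal cycle peaking in July,
  a positive smooth diurnal offset (tmin < tmean everywhere), and positive
  smooth precipitation (≈360–1080 mm·yr⁻¹). A scenario is current climate
  + warming offset on temperatures, × factor on precipitation. Default
  scenario knobs (+2.2 °C wetter; +3.7 °C drier) follow the end-of-century
  global-mean warming of a moderate and a high-end concentration pathway,
  with the drier high-end reflecting the drought mechanism discussed for
  such scenarios.
* Truth: a logistic ("virtual species") surface over standardized predictors;
  the default is GDD-dominant, matching the headline empirical finding that
  growing-season warmth is the top-ranked variable.
* Records: cells drawn proportionally to truth, positions uniform within the
  cell, cited elevations within ±100 m of the cell elevation; injected errors
  (off-grid points, >100 m elevation mismatches, in-cell duplicates) are
  flagged so cleaning can be checked against exact ground truth.

What the generator does **not** emulate: real spatial sampling bias (roads,
herbaria), coordinate precision heterogeneity, niche truncation at range
edges, temporal structure, and real geography. A green recovery test
therefore establishes that the estimator recovers a known smooth niche from
moderately sized clean samples — not that any real map is correct.

## Numerical and design choices

* Equal-area plane throughout: projection/resampling of real rasters is an
  ingestion contract, not part of the method; synthetic grids are generated
  natively equal-area. Latitude (for day length) is y/111.32 km per degree.
* Raster exchange uses plain-text ESRI ASCII grids (nodata −9999), written at
  full double precision so write-then-read round-trips bitwise; the
  environment provides no GeoTIFF-capable package, and the format choice is
  an I/O detail behind `read_raster()`/`write_raster()`.
* Determinism: every stochastic step takes an explicit seed; the pipeline
  derives stage seeds from one master seed by fixed offsets and records them
  in the run manifest together with config and output digests, which is
  sufficient to re-execute a bit-identical run.
* Degenerate inputs: constant predictors are dropped from the feature set
  with a warning; an all-nonpositive heat index makes PET identically zero
  (water balance = annual precipitation); a constant-reference MESS predictor
  scores 0 at the constant and −∞ elsewhere; `current = 0` areas make percent
  changes undefined (reported as NA).
* Scale-downs for test budgets: the acceptance-scale recovery run uses 5
  replicates rather than 15 — the replicate count only tightens the average,
  and the stated recovery bar is already met per replicate — and the example
  pipeline configs use LQ features with 10 hinge knots for speed; all
  defaults remain at the documented values.

## Known limitations

* No categorical/threshold features, bias layers, or cloglog output; no
  bit-compatibility with the Java reference implementation is attempted.
* The AUC test split reuses each replicate's 25% holdout; whether the
  original analyses used an independent partition is unstated.
* Thornthwaite PET underestimates evapotranspiration in windy/arid climates;
  it is used as the simplest temperature-based convention.
* The jackknife "explanatory power" normalization is one defensible reading
  of an under-specified convention and is kept behind a single function.
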