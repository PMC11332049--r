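---
title: "Estimating phenological gradients and shifts from opportunistic observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phenological gradients and shifts from opportunistic observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoshift)
```

## The problem

Plant identification apps and species-reporting platforms generate millions
of presence-only plant records per year. Each record documents that a
species was seen somewhere at some time — nothing about phenological stage,
sampling design, or effort. Because users photograph plants mostly when they
are conspicuous (flowering, for most herbs), the seasonal density of
observations peaks near peak flowering, and robust percentiles of the
observation-date distribution carry phenological signal. `phenoshift`
estimates that signal and relates it to geography and temperature:

1. **Gridding.** Observations are projected onto an equal-area grid
   (default 50 × 50 km in an ETRS89-LAEA-parameterised Lambert azimuthal
   equal-area plane) and pooled per species × year × cell. Cells with fewer
   than `min_count = 25` observations are excluded from direct estimation;
   equal cell areas keep per-cell sample sizes comparable.
2. **Phenometric.** The median observation date (MOD) per cell is the 50th
   percentile of a Weibull distribution fitted to the day-of-year sample,
   bias-corrected by parametric bootstrap. The median is used rather than
   onset because extreme-order statistics are strongly sample-size
   dependent in opportunistic data while central percentiles are not.
3. **Interpolation.** Under-sampled cells are filled by support-vector
   regression of MOD on elevation, latitude and longitude, restricted to
   the area of applicability (AOA) of the trained model.
4. **Thermal time.** Growing degree days (GDD) — cumulative daily mean
   temperature above 5 °C — link inter-annual MOD shifts to temperature
   accumulation.
5. **Inference.** Per species × year, ordinary least squares quantifies the
   bioclimatic gradient `mod = m_elev·elev + m_lat·lat + m_lon·lon + n + ε`
   (Hopkins' bioclimatic law expects roughly +4 d per degree latitude north
   and a positive elevational gradient for spring events); paired Wilcoxon
   signed-rank tests assess inter-annual shifts per cell; a quadratic trend
   describes how gradient strength varies over the season.

## The MOD estimator

For a day-of-year sample $x_1,\dots,x_n$ the estimator:

1. jitters tied integer days uniformly within ±0.5 d (continuous MLE on
   rounded calendar dates),
2. fits a two-parameter Weibull by maximum likelihood. The fit profiles the
   scale ($\hat\lambda(k) = (\tfrac1n\sum x_i^k)^{1/k}$) and solves the
   one-dimensional score equation for the shape in log space, which makes a
   fit cheap enough to be repeated hundreds of times per cell,
3. takes the naive plug-in quantile
   $\hat q = \hat\lambda\,(-\log(1-q))^{1/\hat k}$,
4. draws `n_bootstrap = 250` parametric-bootstrap samples of size $n$ from
   the fitted distribution, recomputes the plug-in estimator on each, and
   subtracts the mean bootstrap bias (one-step correction:
   $\hat q_{bc} = 2\hat q - \overline{q^\ast}$),
5. reports the 2.5/97.5 bootstrap percentiles re-centred on the corrected
   estimate as the confidence interval.

The correction targets the *mean bias* of the plug-in estimator, which is
$O(1/n)$ at the minimum sample size of 25; in the package's Monte-Carlo
checks the plug-in's mean bias of ≈0.6 d at $n=25$ (Weibull shape 2) is
almost entirely removed, while the mean absolute error is essentially
unchanged — the correction removes systematic, not stochastic, error.
(Because naive and corrected estimates share each sample's noise, those
checks measure the naive bias from a large plain Monte-Carlo run and the
removed bias from paired replicates.) Both the naive and corrected estimates are retained
in every output so the effect of the correction stays inspectable. One-step
mean-bias subtraction is used rather than an iterated correction; the
bootstrap percentile CI is used because no stronger interval convention is
required by the downstream analyses (cell-level CIs are reported, not
propagated).

Degenerate samples (all observations on one day) short-circuit to that day
with a zero-width interval. Samples below `min_count` are refused — those
cells are candidates for interpolation instead.

## Gridding choices

The projection is an ellipsoidal Lambert azimuthal equal-area projection
with the standard European parameters (GRS80, centre 52°N 10°E, false
origin 4321000/3210000 m), implemented in closed form and verified against
the CRS's defining point, projective round-trips, geodesic distances and
geodesic cell areas. Cells are half-open, `[x, x + size)`, so each cell
owns its lower and left edges and every point belongs to exactly one cell;
indexing is row-major from the lower-left origin. `build_grid()` places the
origin at the projected minimum of the (densified) bounding-box outline —
a bbox that fits inside one cell yields a 1 × 1 grid — and `grid_spec()`
exposes direct construction for alignment with external reference grids.
Cell covariates are the unweighted mean of elevation pixels intersecting
the cell and the geographic coordinates of the projected cell centroid.
January 1 is DOY 1; years are handled as 365 days with a leap day folded
into the temperature of DOY 59, avoiding cross-year DOY misalignment.

## Interpolation and the area of applicability

The interpolator is ε-regression with a radial-basis kernel on
standardized (elev, lat, lon). At continental scale there is no reason to
expect a parametric form beyond smoothness, and an RBF SVR approximates
the linear-plus-topography surfaces seen in practice well. Hyperparameters
(cost ∈ {1, 10, 100, 1000}, γ ∈ {0.01, 0.1, 1}, ε = 0.1 d) are chosen by
5-fold cross-validation with folds assigned deterministically by cell
order, so training involves no randomness. A constant training response
(which leaves ε-SVR without support vectors) short-circuits to a constant
predictor.

Predictions are only accepted inside the area of applicability: the
dissimilarity index of a target cell is its minimum Euclidean distance in
standardized predictor space to any training cell, normalized by the mean
pairwise training distance; the threshold is the upper whisker
(Q3 + 1.5·IQR) of the training cells' leave-one-out indices. Observed
values are never overwritten, and cells outside the AOA are reported, not
predicted. Gradient regressions use observed cells only by default:
interpolated MODs are deterministic functions of the same covariates the
regression uses, so including them would re-derive the interpolator's
coefficients rather than measure the data (a config switch enables the
inclusive variant for comparison).

## Thermal time and the sign convention

GDD uses the simple averaging formula — daily mean = (tmin + tmax)/2,
increment = max(0, mean − 5 °C), cumulative from January 1 — matching the
convention of agricultural forcing models; no single-sine or upper-cutoff
variant is applied. `gdd_at_mod()` interpolates the cumulative curve
linearly at fractional MODs with GDD(0) = 0.

Shift orientation is fixed package-wide as **year 2 − year 1** (2021 −
2020 in a two-year design): a positive MOD shift means earlier flowering
in year 1. For the GDD comparison, both years' accumulation curves are
evaluated at a **common per-cell reference MOD** (the first year's, by
default). Evaluating each year at its own MOD would compare forcing sums
that a temperature-driven phenology keeps constant by construction — on
thermally coupled data both years would sit at the forcing threshold and
the difference would be noise around zero. At a common day, a warmer year
has accumulated strictly more degree-days, so earlier flowering (positive
MOD shift, year1 warmer) pairs with a negative GDD shift: the
complementary-sign relationship the package tests for. The own-year
evaluation remains available via `pipeline_config(gdd_eval = "own_year")`.

## Inference details

- OLS is unweighted across cells regardless of per-cell n.
- The Holm step-down family is the three slope p-values of one
  species × year model; the family scope is a deliberate minimal choice
  and `holm_adjust()` is exposed for any wider family a user prefers.
- The inter-annual test is a Wilcoxon signed-rank test on per-cell paired
  MOD differences (the faithful reading of a "paired" design; a rank-sum
  test would ignore the pairing), two-sided; all-zero differences return
  p = 1 with a degenerate flag.
- Species are classified spring-flowering when the reference-year median
  of cell MODs is strictly before DOY 172 (astronomical summer onset);
  DOY 172 itself is summer.
- The seasonal trend fits `coefficient ~ mod + mod²` by OLS and reports
  vertex and concavity; a hump-shaped (negative-concavity) trend peaking
  near the spring–summer transition is the expected signature.

## What the synthetic generator emulates — and what it does not

`synth_landscape()` builds a 20 × 20-cell (default) equal-area landscape
with log-normal elevations (median ≈300 m, truncated at 2500 m), spanning
~10° of latitude at 50 km cells — wide enough to express gradients of a
few days per degree. `make_true_surface()` evaluates a known linear
median-DOY surface; `sample_observations()` draws per-cell counts from a
Poisson or negative-binomial effort model with hotspot multipliers
(emulating the clustering of opportunistic records around population
centres) and observation dates from a normal or Weibull family around the
cell's true median (the observed single-peak, roughly symmetric
observation curves justify either; both are provided because the real
shape is species-dependent). Dates are continuous, rounded to integer DOY;
coordinates are uniform within the projected cell, so every synthetic
dataset also exercises the projection round-trip.
`make_gdd_coupled_observations()` instead places the true median at the
day a GDD threshold is crossed, giving the temperature-coupling analyses a
known answer.

Defaults used by the verification suite: dispersion 10 d (within the
spread of single-species observation curves over a season), baseline
effort 35–120 observations per cell depending on the check, gradient
4 d/° latitude, 20 d/1000 m elevation. Test problem sizes (36–100 cells,
20–50 replicates, 100–250 bootstrap draws) were chosen as the smallest
sizes at which the Monte-Carlo noise of each check is well below its
tolerance.

Not emulated: real species ranges and range edges, weekday/holiday effort
cycles, weather-driven observation gaps, multi-species identification
confusion, and coastline/land-use masking. Passing recovery tests
therefore demonstrate the *estimators* are correct and calibrated under
the stated statistical structure — they do not certify robustness to every
bias of real opportunistic data, which is why the pipeline reports
coverage, provenance and exclusion diagnostics at each stage.

## Numerical choices and degenerate inputs

- Weibull MLE: score root bracketed in shape ∈ [10⁻³, 10⁵] on a
  max-rescaled sample (the shape is scale-invariant), tolerance 10⁻¹⁰;
  non-bracketing or non-finite likelihood raises an error rather than
  returning a silent fallback.
- Ties: jitter ±0.5 d under the estimator's seed; `fit_weibull()` itself
  is deterministic for a given numeric sample.
- Percentile CIs are clamped to contain the corrected point estimate (the
  re-centred percentile interval can exclude it only through bootstrap
  skew at tiny n).
- All generators and estimators save and restore the caller's RNG state;
  seeds derive deterministically from a single base seed per run.
- Empty observation sets, empty MOD grids and cells with no temperature
  coverage are defined results or named errors, never silent drops —
  counts of read/dropped/sub-threshold/estimated/interpolated records are
  carried in the result manifest.

## Known limitations

- The ellipsoidal inverse projection uses the standard authalic-latitude
  series (sub-millimetre over Europe); antipodal robustness is untested
  and irrelevant at continental extents.
- The AOA threshold follows the whisker rule on leave-one-out training
  dissimilarities; with fewer than ~15 training cells the threshold
  estimate itself is noisy, and the package requires ≥10 observed cells
  before interpolating at all.
- The bias correction assumes the Weibull family is adequate; for strongly
  bimodal observation curves (e.g. double-flowering species) the MOD
  itself is a questionable phenometric, and no family-misfit diagnostic is
  emitted beyond the retained naive/corrected pair.
- NetCDF temperature sources are expected to be converted to the package's
  long CSV layout (`cell_id, year, day, tmin, tmax`) or pixel tables for
  `rescale_temperature()`; no binary gridded formats are read directly.
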