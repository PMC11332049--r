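# phenoshift

Phenological gradients and inter-annual shifts estimated from
opportunistic, presence-only plant observations.

Identification apps and species-reporting platforms produce massive
streams of records that say only *this species, here, on this date*. For
species that are mostly photographed while flowering, the seasonal
distribution of those records peaks near peak flowering, so robust
percentiles of the observation-date distribution are usable phenometrics.
`phenoshift` is for ecologists who want to turn such record streams into
per-grid-cell flowering dates and test how those dates move with
geography, between years, and with temperature accumulation.

## What it computes

- **MOD (median observation date)** per species × year × 50 × 50 km
  equal-area grid cell: the 50th percentile of a maximum-likelihood
  Weibull fit to the day-of-year sample, bias-corrected by parametric
  bootstrap (`2·q̂ − mean(q*)` over bootstrap plug-in estimates), with
  percentile-bootstrap confidence intervals. Cells with fewer than 25
  observations are not estimated directly.
- **Spatial interpolation** of MOD for under-sampled cells:
  radial-basis support-vector regression on elevation, latitude and
  longitude, accepted only inside the **area of applicability** (a
  dissimilarity-index threshold derived from the training cells).
- **Growing degree days** (cumulative daily mean temperature above 5 °C)
  and their value at the MOD, linking phenological shifts to thermal
  time.
- **Bioclimatic gradients** per species × year by OLS,

  `mod = m_elev·elev + m_lat·lat + m_lon·lon + n + ε`,

  with Bonferroni–Holm adjusted coefficient p-values — the regression
  form of Hopkins' bioclimatic law (≈ +4 d per degree latitude north for
  spring events) — plus paired Wilcoxon signed-rank tests of inter-annual
  shifts, spring/summer classification at DOY 172, and the quadratic
  seasonal trend of gradient strength.
- **Synthetic data with known truth**: landscapes, clustered observation
  effort, linear median-DOY surfaces, daily temperature fields and
  GDD-coupled phenology, so every stage is testable by parameter
  recovery.

## Worked example

Generate a two-year synthetic dataset with a known 4 d/° latitudinal
gradient, a 20 d/1000 m elevational gradient and a +6 d shift in the
second year, then run the full pipeline:

```r
library(phenoshift)

land  <- synth_landscape(n_side = 10, seed = 1)          # 100 cells, 50 km
surf  <- true_surface(beta0 = -60, beta_elev = 20, beta_lat = 4,
                      beta_lon = 0.5, year_shift = 6, dispersion = 10)
truth <- make_true_surface(land$covariates, surf)
obs   <- sample_observations(truth,
                             effort_model(n_hotspots = 5, mean_obs_per_cell = 60),
                             surf, years = c(2020, 2021), seed = 2,
                             grid = land$grid)           # 11,998 records

res <- run_pipeline(obs, land$grid, land$covariates,
                    config = pipeline_config(n_bootstrap = 250, seed = 3))
res
#> phenology pipeline result
#>   observations: 11998 assigned, 11998 retained after min-count filter
#>   cells estimated: 200 (+0 interpolated)
#>   gradient fits: 2 species-year models
#>   median inter-annual shift (year2-year1): 5.94 d (p=3.96e-18)

subset(res$gradient_fits, year == 2020,
       select = c(species, m_elev_per_km, m_lat, m_lon, r2, n_cells))
#>              species m_elev_per_km    m_lat     m_lon       r2 n_cells
#> 1 Synthetica exempli      20.75199 4.043701 0.6679313 0.981319     100

res$season
#>              species median_mod_reference_year  class threshold_doy
#> 1 Synthetica exempli                  161.5573 spring           172
```

The fitted gradients (20.75 d/1000 m, 4.04 d/°lat, 0.67 d/°lon) recover
the generating surface; the paired Wilcoxon test finds the induced +6 d
shift (median 5.94 d, year 2 − year 1); and the species classifies as
spring-flowering because its median cell MOD (161.6) falls before
DOY 172.

Real data enter through `read_observations()` (CSV with species,
longitude, latitude, ISO-8601 date; multi-file pooling with a column
map), `cell_covariates()` for elevation pixels, and
`read_temperature_csv()` / `rescale_temperature()` for daily
tmin/tmax grids.

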