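test_that("observation reader parses, validates, and pools CSV sources", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(species = "a", longitude = c(10, 11, 12),
                       latitude = c(50, 51, 52),
                       date = c("2020-03-01", "2020-12-31", "2021-01-01")),
            f1, row.names = FALSE)
  write.csv(data.frame(species = "a", longitude = c(10, 10),
                       latitude = c(95, 50),      # first row invalid
                       date = c("2020-06-01", "not-a-date")),
            f2, row.names = FALSE)
  obs <- read_observations(f1)
  expect_equal(nrow(obs), 3)
  expect_equal(obs$doy, c(61, 366, 1))   # 2020 is a leap year
  expect_equal(obs$year, c(2020, 2020, 2021))
  # invalid rows dropped and counted; pooling sums per-source retained rows
  pooled <- read_observations(c(f1, f2))
  expect_equal(nrow(pooled), 3)
  expect_equal(unname(attr(pooled, "dropped")["bad_coord"]), 1)
  expect_equal(unname(attr(pooled, "dropped")["bad_date"]), 1)
  expect_equal(unname(attr(pooled, "per_source")), c(3, 0))
  expect_error(read_observations(f1, column_map = c(species = "sp",
                                                    lon = "longitude",
                                                    lat = "latitude",
                                                    date = "date")), "sp")
  # custom column names resolve through the map
  f3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(taxon = "b", x = 10, y = 50, when = "2020-05-15"),
            f3, row.names = FALSE)
  obs3 <- read_observations(f3, column_map = c(species = "taxon", lon = "x",
                                               lat = "y", date = "when"))
  expect_equal(obs3$doy, 136)
})

test_that("observation and temperature writers round-trip through CSV", {
  ls <- tiny_landscape(4, seed = 61)
  surf <- true_surface(beta0 = -60, dispersion = 8)
  tm <- make_true_surface(ls$covariates, surf)
  obs <- sample_observations(tm, effort_model(mean_obs_per_cell = 10),
                             surf, 2020, seed = 62, grid = ls$grid)
  f <- tempfile(fileext = ".csv")
  paths <- write_observations(obs, f)
  expect_true(file.exists(paths[2]))   # truth sidecar JSON
  back <- read_observations(f)
  expect_equal(nrow(back), nrow(obs))
  expect_equal(back$doy, obs$doy)
  expect_equal(back$lon, obs$lon, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(truth$surface$beta0, -60)
  # temperature cube round-trip
  cube <- synth_temperature(ls$covariates, synthetic_climate(), seed = 63)
  tf <- tempfile(fileext = ".csv")
  write_temperature_csv(cube, tf)
  cube2 <- read_temperature_csv(tf)
  expect_equal(cube2$cell_id, cube$cell_id)
  expect_equal(cube2$tmin, unname(cube$tmin), tolerance = 1e-9)
  expect_equal(cube2$tmax, unname(cube$tmax), tolerance = 1e-9)
  # gaps are refused with the missing range named
  long <- read.csv(tf)
  write.csv(long[-1, ], tf, row.names = FALSE)
  expect_error(read_temperature_csv(tf), "gap")
})

test_that("pipeline runs end-to-end, reproducibly, honouring the config", {
  ls <- tiny_landscape(6, seed = 71)
  surf <- true_surface(beta0 = -60, beta_elev = 20, beta_lat = 4,
                       beta_lon = 0.5, year_shift = 6, dispersion = 8)
  tm <- make_true_surface(ls$covariates, surf)
  obs <- sample_observations(tm, effort_model(n_hotspots = 0,
                                              mean_obs_per_cell = 40),
                             surf, c(2020, 2021), seed = 72, grid = ls$grid)
  cfg <- pipeline_config(n_bootstrap = 100, seed = 73)
  res <- run_pipeline(obs, ls$grid, ls$covariates, config = cfg)
  expect_s3_class(res, "pheno_result")
  # CIs of the gradient fit cover the generating coefficients
  fit <- attr(fit_gradient_model(
    res$mod_observed[res$mod_observed$year == 2020, ], ls$covariates), "fit")
  ci <- confint(fit)
  expect_gt(4, ci["lat", 1]); expect_lt(4, ci["lat", 2])
  expect_gt(0.02, ci["elev", 1]); expect_lt(0.02, ci["elev", 2])
  # the induced year shift appears in the paired test
  expect_equal(res$wilcoxon$median_shift, 6, tolerance = 2)
  expect_lt(res$wilcoxon$wilcoxon_p, 0.01)
  # reproducibility: identical config and inputs, identical outputs
  res2 <- run_pipeline(obs, ls$grid, ls$covariates, config = cfg)
  expect_identical(res$mod_filled, res2$mod_filled)
  expect_identical(res$gradient_fits, res2$gradient_fits)
  # interpolation disabled: no interpolated rows anywhere
  res_no <- run_pipeline(obs, ls$grid, ls$covariates,
                         config = pipeline_config(n_bootstrap = 100, seed = 73,
                                                  interpolate = FALSE))
  expect_false(any(res_no$mod_filled$provenance == "interpolated"))
  # manifest echoes the configuration
  expect_equal(res$manifest$config$min_count, 25)
  expect_equal(res$manifest$seed, 73)
  # stage outputs write to disk with the manifest
  out <- tempfile()
  files <- write_results(res, out)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "gradient_fits.csv")))
})

test_that("pipeline stages compose to the same result as run_pipeline", {
  ls <- tiny_landscape(5, seed = 81)
  surf <- true_surface(beta0 = -60, dispersion = 8)
  tm <- make_true_surface(ls$covariates, surf)
  obs <- sample_observations(tm, effort_model(mean_obs_per_cell = 40),
                             surf, 2020, seed = 82, grid = ls$grid)
  cfg <- pipeline_config(n_bootstrap = 100, seed = 83, interpolate = FALSE)
  res <- run_pipeline(obs, ls$grid, ls$covariates, config = cfg)
  manual <- mod_table(assign_and_aggregate(obs, ls$grid, cfg$min_count),
                      q = cfg$q, n_bootstrap = cfg$n_bootstrap,
                      seed = cfg$seed, min_count = cfg$min_count)
  expect_equal(res$mod_observed$mod, manual$mod)
  expect_equal(res$mod_observed$cell_id, manual$cell_id)
})
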