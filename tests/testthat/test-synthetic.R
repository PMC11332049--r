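test_that("true surface evaluates the linear bioclimatic formula", {
  cov <- data.frame(cell_id = 1:3, elev = c(0, 500, 0),
                    lat = c(50, 50, 51), lon = c(10, 10, 10))
  # constant surface
  s0 <- true_surface(beta0 = 150, beta_elev = 0, beta_lat = 0, beta_lon = 0)
  expect_equal(make_true_surface(cov, s0)$true_median, rep(150, 3))
  # one degree latitude north = +4 days
  s_lat <- true_surface(beta0 = -50, beta_elev = 0, beta_lat = 4, beta_lon = 0)
  m <- make_true_surface(cov, s_lat)$true_median
  expect_equal(m[3] - m[1], 4)
  # 500 m at 20 d / 1000 m = +10 days
  s_elev <- true_surface(beta0 = 150, beta_elev = 20, beta_lat = 0, beta_lon = 0)
  m <- make_true_surface(cov, s_elev)$true_median
  expect_equal(m[2] - m[1], 10)
  # clipping warns; missing covariate errors with the cell named
  expect_warning(make_true_surface(cov, true_surface(beta0 = 400, beta_elev = 0,
                                                     beta_lat = 0, beta_lon = 0)),
                 "clipped")
  cov$elev[2] <- NA
  expect_error(make_true_surface(cov, s0), "2")
})

test_that("observation sampling is seeded, centred, and degenerate at tiny dispersion", {
  ls <- tiny_landscape(4)
  cov1 <- ls$covariates[1, , drop = FALSE]
  tm <- data.frame(cell_id = cov1$cell_id, true_median = 150)
  eff <- effort_model(n_hotspots = 0, mean_obs_per_cell = 50)
  # near-zero dispersion collapses all dates onto the true median
  s_tiny <- true_surface(dispersion = 0.1, shape_family = "normal")
  obs <- sample_observations(tm, eff, s_tiny, 2020, seed = 5, grid = ls$grid)
  expect_true(all(obs$doy == 150))
  # identical seed, identical table; different seed differs
  s10 <- true_surface(dispersion = 10, shape_family = "normal")
  a <- sample_observations(tm, eff, s10, c(2020, 2021), seed = 9, grid = ls$grid)
  b <- sample_observations(tm, eff, s10, c(2020, 2021), seed = 9, grid = ls$grid)
  expect_identical(a, b)
  d <- sample_observations(tm, eff, s10, c(2020, 2021), seed = 10, grid = ls$grid)
  expect_false(identical(nrow(a) == nrow(d) && all(a$doy == d$doy), TRUE))
  # sample median concentrates on the true median (normal family, n = 10000)
  big <- sample_observations(tm, effort_model(n_hotspots = 0,
                                              mean_obs_per_cell = 10000),
                             s10, 2020, seed = 6, grid = ls$grid)
  expect_lt(abs(median(big$doy) - 150), 0.5 + 1e-9)
  # weibull family honours the requested median too
  sw <- true_surface(dispersion = 10, shape_family = "weibull")
  bw <- sample_observations(tm, effort_model(n_hotspots = 0,
                                             mean_obs_per_cell = 10000),
                            sw, 2020, seed = 6, grid = ls$grid)
  expect_lt(abs(median(bw$doy) - 150), 1.5)
  expect_lt(abs(sd(bw$doy) - 10), 1)
})

test_that("year shift moves the median of later years", {
  ls <- tiny_landscape(4)
  tm <- data.frame(cell_id = ls$covariates$cell_id[1], true_median = 150)
  s <- true_surface(dispersion = 5, year_shift = 7, shape_family = "normal")
  obs <- sample_observations(tm, effort_model(n_hotspots = 0,
                                              mean_obs_per_cell = 3000),
                             s, c(2020, 2021), seed = 4, grid = ls$grid)
  m1 <- median(obs$doy[obs$year == 2020])
  m2 <- median(obs$doy[obs$year == 2021])
  expect_lt(abs((m2 - m1) - 7), 1)
})

test_that("synthetic temperature follows the stated formula", {
  cov <- data.frame(cell_id = 1:3, elev = c(0, 1000, 0),
                    lat = c(50, 50, 52), lon = 10)
  # all gradients off: constant field everywhere
  c0 <- synthetic_climate(t_mean_annual = 12, seasonal_amplitude = 0,
                          lapse_rate = 0, lat_gradient = 0,
                          daily_noise_sd = 0, diurnal_range = 6)
  cube <- synth_temperature(cov, c0, seed = 1)
  expect_true(all((cube$tmin + cube$tmax) / 2 == 12))
  # diurnal range exact by construction when noise-free
  expect_true(all(abs(cube$tmax - cube$tmin - 6) < 1e-12))
  # 1000 m elevation difference = lapse_rate, every day
  c1 <- synthetic_climate(seasonal_amplitude = 10, lapse_rate = 6.5,
                          lat_gradient = 0.7, daily_noise_sd = 0)
  cube1 <- synth_temperature(cov, c1, seed = 1)
  tmean <- (cube1$tmin + cube1$tmax) / 2
  expect_equal(tmean[1, ] - tmean[2, ], rep(6.5, 365))
  # 2 degrees latitude = 2 * lat_gradient, every day
  expect_equal(tmean[1, ] - tmean[3, ], rep(1.4, 365))
  # seasonal term peaks at phase_doy
  expect_equal(which.max(tmean[1, ]), c1$phase_doy)
  # seeded reproducibility with noise on
  cn <- synthetic_climate(daily_noise_sd = 2)
  expect_identical(synth_temperature(cov, cn, seed = 3),
                   synth_temperature(cov, cn, seed = 3))
})

test_that("GDD-coupled observations place the true median at threshold crossing", {
  ls <- tiny_landscape(3)
  cells <- ls$covariates$cell_id
  eff <- effort_model(n_hotspots = 0, mean_obs_per_cell = 200)
  # constant 15 C: 10 C day accumulation, threshold 100 crossed on day 10
  cube <- constant_cube(cells, 15)
  obs <- make_gdd_coupled_observations(cube, 100, eff, dispersion = 0.1,
                                       seed = 2, grid = ls$grid)
  expect_equal(attr(obs, "truth")$true_mod$true_median, rep(10, length(cells)))
  # threshold 0: first day with accumulation; warm all year means day 1
  obs0 <- make_gdd_coupled_observations(cube, 0, eff, dispersion = 0.1,
                                        seed = 2, grid = ls$grid)
  expect_equal(attr(obs0, "truth")$true_mod$true_median, rep(1, length(cells)))
  # cells never reaching the threshold are flagged; all-unreachable errors
  cold <- constant_cube(cells, 4)
  expect_error(make_gdd_coupled_observations(cold, 100, eff, 1, seed = 1,
                                             grid = ls$grid),
               "never reached")
  mixed <- cube
  mixed$tmin[1, ] <- -10; mixed$tmax[1, ] <- 0
  obs_m <- make_gdd_coupled_observations(mixed, 100, eff, dispersion = 1,
                                         seed = 2, grid = ls$grid)
  expect_equal(attr(obs_m, "truth")$unreached_cells, cells[1])
  expect_false(cells[1] %in% attr(obs_m, "truth")$true_mod$cell_id)
})

test_that("effort model concentrates observations in hotspot cells", {
  ls <- tiny_landscape(6)
  surf <- true_surface(beta0 = -60, dispersion = 8)
  tm <- make_true_surface(ls$covariates, surf)
  eff <- effort_model(n_hotspots = 3, hotspot_multiplier = 20,
                      mean_obs_per_cell = 30,
                      count_family = "negative_binomial",
                      hotspot_concentration = 5)
  obs <- sample_observations(tm, eff, surf, 2020, seed = 8, grid = ls$grid)
  truth <- attr(obs, "truth")
  agg <- assign_and_aggregate(obs, ls$grid, min_count = 1)
  n_by_cell <- vapply(agg$samples, `[[`, integer(1), "n")
  ids <- vapply(agg$samples, `[[`, integer(1), "cell_id")
  hot <- ids %in% truth$hotspot_cells
  expect_gt(mean(n_by_cell[hot]), 3 * mean(n_by_cell[!hot]))
  expect_true(all(n_by_cell >= 0))
})
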