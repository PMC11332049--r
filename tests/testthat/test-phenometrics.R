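test_that("Weibull quantile matches the closed form and is monotone", {
  expect_equal(weibull_quantile(list(shape = 1, scale = 100), 0.5),
               100 * log(2), tolerance = 1e-6)
  expect_equal(weibull_quantile(list(shape = 2, scale = 180), 0.5),
               180 * log(2)^(1 / 2), tolerance = 1e-6)
  expect_error(weibull_quantile(list(shape = 2, scale = 180), 0), "strictly")
  expect_error(weibull_quantile(list(shape = 2, scale = 180), 1), "strictly")
  # monotone in q for a spread of shapes
  for (k in c(0.5, 1, 2, 5, 10)) {
    qs <- weibull_quantile(list(shape = k, scale = 160), seq(0.05, 0.95, 0.05))
    expect_true(all(diff(qs) > 0))
  }
  # q -> 0 approaches the location (lower support limit)
  expect_lt(weibull_quantile(list(shape = 2, scale = 180), 1e-12), 1e-3)
  expect_equal(weibull_quantile(list(shape = 2, scale = 180, location = 40), 1e-12),
               40, tolerance = 1e-3)
})

test_that("maximum-likelihood fit is consistent and order-invariant", {
  set.seed(21)
  x <- rweibull(10000, 5, 160)
  f <- fit_weibull(x)
  expect_gt(f$shape, 4.8); expect_lt(f$shape, 5.2)
  expect_gt(f$scale, 158); expect_lt(f$scale, 162)
  # exponential data sit at the shape = 1 sub-family boundary
  set.seed(22)
  fe <- fit_weibull(rexp(10000, 1 / 50))
  expect_equal(fe$shape, 1, tolerance = 0.05)
  # permutation invariance
  f2 <- fit_weibull(rev(x))
  expect_equal(f2$shape, f$shape)
  expect_equal(f2$scale, f$scale)
  # guards
  expect_error(fit_weibull(150), "at least 2")
  expect_error(fit_weibull(c(150, 150, 150)), "identical")
  expect_error(fit_weibull(c(-1, 5, 10)), "finite and greater")
})

test_that("fast profiled MLE agrees with the fitdistrplus oracle", {
  set.seed(23)
  for (k in c(1.5, 4, 9)) {
    x <- rweibull(400, k, 150)
    mine <- fit_weibull(x)
    ref <- fitdistrplus::fitdist(x, "weibull")
    expect_equal(mine$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
    expect_equal(mine$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
  }
})

test_that("bias-corrected percentile estimates the true median", {
  set.seed(24)
  x <- round(rweibull(1000, 5, 160))
  est <- estimate_percentile(x, q = 0.5, n_bootstrap = 250, seed = 31)
  true_med <- 160 * log(2)^(1 / 5)   # 148.69
  expect_lt(abs(est$mod - true_med), 1.5)
  expect_true(est$ci_low <= est$mod && est$mod <= est$ci_high)
  expect_identical(est$method_tag, "bias_corrected")
  # reproducible under the seed
  est2 <- estimate_percentile(x, q = 0.5, n_bootstrap = 250, seed = 31)
  expect_identical(est, est2)
  # degenerate sample short-circuits
  dg <- estimate_percentile(rep(140, 30), seed = 1)
  expect_equal(c(dg$mod, dg$ci_low, dg$ci_high), c(140, 140, 140))
  expect_identical(dg$method_tag, "degenerate")
  # refusal below the minimum count names the reason
  expect_error(estimate_percentile(1:10, seed = 1), "min_count")
})

test_that("corrected estimator tracks the empirical median across shapes at large n", {
  set.seed(25)
  for (k in c(1, 3, 10)) {
    x <- rweibull(10000, k, 160)
    est <- estimate_percentile(round(pmax(x, 1)), n_bootstrap = 100, seed = 41)
    expect_lt(abs(est$mod - median(x)), 1)
  }
})

test_that("confidence intervals shrink with sample size", {
  set.seed(26)
  pop <- rweibull(400, 2, 160)
  small <- estimate_percentile(round(pop[1:25]), n_bootstrap = 250, seed = 51)
  large <- estimate_percentile(round(pop), n_bootstrap = 250, seed = 51)
  expect_lt(large$ci_high - large$ci_low, small$ci_high - small$ci_low)
})

test_that("mod_table estimates every retained sample and summarises species medians", {
  doys <- round(rnorm(40, 150, 8))
  samples <- list(
    list(species = "a", year = 2020, cell_id = 1L, doys = doys, n = 40L),
    list(species = "a", year = 2020, cell_id = 2L, doys = doys, n = 40L),
    list(species = "a", year = 2020, cell_id = 3L, doys = doys, n = 40L))
  mt <- mod_table(samples, n_bootstrap = 100, seed = 2)
  expect_equal(nrow(mt), 3)
  # identical data but distinct per-cell seeds: estimates agree to the
  # bootstrap's own uncertainty
  expect_lt(diff(range(mt$mod)), 1.5)
  expect_true(all(mt$provenance == "observed"))
  sm <- attr(mt, "species_median")
  expect_equal(nrow(sm), 1)
  expect_equal(sm$median_mod, median(mt$mod))
  # empty input gives an empty grid
  expect_equal(nrow(mod_table(list(), seed = 1)), 0)
})

test_that("cell MODs recover a latitudinal gradient from generated observations", {
  ls <- tiny_landscape(5, seed = 31)
  surf <- true_surface(beta0 = -60, beta_elev = 0, beta_lat = 4, beta_lon = 0,
                       dispersion = 6)
  tm <- make_true_surface(ls$covariates, surf)
  obs <- sample_observations(tm, effort_model(n_hotspots = 0,
                                              mean_obs_per_cell = 80),
                             surf, 2020, seed = 32, grid = ls$grid)
  mt <- mod_table(assign_and_aggregate(obs, ls$grid, 25),
                  n_bootstrap = 100, seed = 33)
  d <- merge(mt, ls$covariates, by = "cell_id")
  slope <- coef(lm(mod ~ lat, data = d))["lat"]
  expect_equal(unname(slope), 4, tolerance = 0.15)
})
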