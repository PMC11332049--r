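# Synthetic-data generators with known ground truth: observation effort,
# observation-date distributions over a linear bioclimatic surface, daily
# temperature fields, and growing-degree-day-coupled phenology. Everything
# downstream is verifiable by parameter recovery against the metadata these
# generators attach.

#' Ground-truth bioclimatic surface parameters
#'
#' The generating counterpart of the gradient regression: the true median
#' observation date per cell is a linear function of elevation, latitude and
#' longitude, plus an inter-annual shift.
#'
#' @param beta0 Intercept (DOY).
#' @param beta_elev Days per 1000 m elevation.
#' @param beta_lat Days per degree latitude.
#' @param beta_lon Days per degree longitude.
#' @param year_shift Days added per year index (0 for the first year).
#' @param dispersion Spread (sd, days) of observation dates around the
#'   median; must be positive.
#' @param shape_family Date distribution family: `"normal"` or `"weibull"`.
#' @return A list of class `true_surface`.
#' @export
true_surface <- function(beta0 = 150, beta_elev = 20, beta_lat = 4,
                         beta_lon = 0.5, year_shift = 0, dispersion = 10,
                         shape_family = c("normal", "weibull")) {
  shape_family <- match.arg(shape_family)
  stopifnot(dispersion > 0)
  structure(list(beta0 = beta0, beta_elev = beta_elev, beta_lat = beta_lat,
                 beta_lon = beta_lon, year_shift = year_shift,
                 dispersion = dispersion, shape_family = shape_family),
            class = "true_surface")
}

#' Observation-effort model
#'
#' Emulates spatially clustered recording effort: a few hotspot cells (think
#' cities) receive a multiple of the baseline effort, and realised counts are
#' Poisson or negative-binomial around the cell expectation.
#'
#' @param n_hotspots Number of hotspot cells.
#' @param hotspot_concentration Negative-binomial size parameter (ignored for
#'   Poisson counts); smaller = more overdispersed.
#' @param mean_obs_per_cell Baseline expected observations per cell (> 0).
#' @param hotspot_multiplier Effort multiple in hotspot cells.
#' @param count_family `"poisson"` or `"negative_binomial"`.
#' @return A list of class `effort_model`.
#' @export
effort_model <- function(n_hotspots = 5, hotspot_concentration = 2,
                         mean_obs_per_cell = 50, hotspot_multiplier = 10,
                         count_family = c("poisson", "negative_binomial")) {
  count_family <- match.arg(count_family)
  stopifnot(mean_obs_per_cell > 0, n_hotspots >= 0, hotspot_multiplier >= 1)
  structure(list(n_hotspots = n_hotspots,
                 hotspot_concentration = hotspot_concentration,
                 mean_obs_per_cell = mean_obs_per_cell,
                 hotspot_multiplier = hotspot_multiplier,
                 count_family = count_family),
            class = "effort_model")
}

#' Synthetic climate parameters
#'
#' Daily mean temperature = annual mean + seasonal sine + elevational lapse +
#' latitudinal gradient + iid noise; tmin/tmax are the mean -/+ half the
#' diurnal range.
#'
#' @param t_mean_annual Annual mean at sea level and the southern grid edge
#'   (deg C).
#' @param seasonal_amplitude Seasonal half-range (deg C).
#' @param phase_doy DOY at which the seasonal term peaks.
#' @param lapse_rate Cooling per 1000 m elevation (deg C).
#' @param lat_gradient Cooling per degree latitude north of the grid minimum
#'   (deg C).
#' @param daily_noise_sd iid daily noise sd (deg C, >= 0).
#' @param diurnal_range tmax - tmin (deg C, >= 0).
#' @return A list of class `synthetic_climate`.
#' @export
synthetic_climate <- function(t_mean_annual = 9, seasonal_amplitude = 10,
                              phase_doy = 200, lapse_rate = 6.5,
                              lat_gradient = 0.7, daily_noise_sd = 1.5,
                              diurnal_range = 8) {
  stopifnot(daily_noise_sd >= 0, diurnal_range >= 0)
  structure(list(t_mean_annual = t_mean_annual,
                 seasonal_amplitude = seasonal_amplitude,
                 phase_doy = phase_doy, lapse_rate = lapse_rate,
                 lat_gradient = lat_gradient,
                 daily_noise_sd = daily_noise_sd,
                 diurnal_range = diurnal_range),
            class = "synthetic_climate")
}

#' Synthetic landscape: grid plus per-cell covariates
#'
#' A square equal-area grid in central Europe with log-normally distributed
#' cell elevations truncated to [0, 2500] m. The default 20 x 20 cells of
#' 50 km span roughly 10 degrees of latitude, enough to express the studied
#' gradients at desk scale.
#'
#' @param n_side Cells per side.
#' @param cell_size Cell edge (metres).
#' @param seed RNG seed for elevations.
#' @param elev_meanlog,elev_sdlog Log-normal elevation parameters.
#' @param origin_x,origin_y Grid origin in the projected plane (metres);
#'   defaults centre the landscape near the projection centre.
#' @return List with `grid` (a `grid_spec`) and `covariates`
#'   (`cell_id`, `elev`, `lat`, `lon`).
#' @export
synth_landscape <- function(n_side = 20, cell_size = 50000, seed = 1,
                            elev_meanlog = log(300), elev_sdlog = 1,
                            origin_x = 4321000 - n_side / 2 * cell_size,
                            origin_y = 3210000 - n_side / 2 * cell_size) {
  grid <- grid_spec(origin_x, origin_y, n_side, n_side, cell_size)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- n_side * n_side
  elev <- pmin(stats::rlnorm(n, elev_meanlog, elev_sdlog), 2500)
  ctr <- cell_centroids(grid)
  geo <- laea_unproject(ctr$x, ctr$y, grid$crs)
  list(grid = grid,
       covariates = data.frame(cell_id = ctr$cell_id, elev = elev,
                               lat = geo$lat, lon = geo$lon))
}

#' Evaluate the true median-DOY surface on cell covariates
#'
#' `true_median = beta0 + beta_elev * elev/1000 + beta_lat * lat +
#' beta_lon * lon`, with centroid latitude/longitude in degrees. Values are
#' clipped to the calendar [1, 365] with a warning.
#'
#' @param covariates data.frame `cell_id`, `elev`, `lat`, `lon`.
#' @param surface A [true_surface()] object.
#' @return data.frame `cell_id`, `true_median`.
#' @export
make_true_surface <- function(covariates, surface) {
  stopifnot(inherits(surface, "true_surface"))
  need <- c("cell_id", "elev", "lat", "lon")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariates lack columns: ", paste(miss, collapse = ", "))
  bad <- !is.finite(covariates$elev) | !is.finite(covariates$lat) |
    !is.finite(covariates$lon)
  if (any(bad)) {
    stop("non-finite covariates for cell(s): ",
         paste(covariates$cell_id[bad], collapse = ", "))
  }
  m <- surface$beta0 + surface$beta_elev * covariates$elev / 1000 +
    surface$beta_lat * covariates$lat + surface$beta_lon * covariates$lon
  if (any(m < 1 | m > 365)) {
    warning("true median clipped to [1, 365] in ", sum(m < 1 | m > 365), " cell(s)")
    m <- pmin(pmax(m, 1), 365)
  }
  data.frame(cell_id = covariates$cell_id, true_median = m)
}

# Weibull shape giving sd ~= `disp` at median `med` (scale follows from the
# median); solved on log-shape by root-finding on the sd ratio.
.weibull_from_median_sd <- function(med, disp) {
  sd_ratio <- function(k) {
    s <- med / log(2)^(1 / k)
    s * sqrt(gamma(1 + 2 / k) - gamma(1 + 1 / k)^2) / disp - 1
  }
  k <- tryCatch(
    stats::uniroot(function(u) sd_ratio(exp(u)), c(log(0.2), log(2000)),
                   tol = 1e-8)$root,
    error = function(e) log(5))
  shape <- exp(k)
  list(shape = shape, scale = med / log(2)^(1 / shape))
}

#' Sample presence-only observations over a true surface
#'
#' For each cell and year, draws a realised observation count from the
#' effort model, then observation dates from the configured family centred
#' (in median) on the cell's true median plus the cumulative year shift.
#' Dates are drawn in continuous time and rounded to integer DOY in
#' [1, 365]; coordinates are uniform inside the projected cell and
#' inverse-projected to lon/lat. The generating parameters travel along as
#' the `truth` attribute so recovery tests can close the loop.
#'
#' @param true_medians data.frame `cell_id`, `true_median` (from
#'   [make_true_surface()]).
#' @param effort An [effort_model()].
#' @param surface The [true_surface()] used (dispersion, family, year shift).
#' @param years Vector of year labels (e.g. `c(2020, 2021)`); the first gets
#'   year index 0.
#' @param seed Integer RNG seed; identical seed gives identical output.
#' @param grid The `grid_spec` the cells refer to (for coordinates).
#' @param species Species label written on every record.
#' @return Observation data.frame (`species`, `lon`, `lat`, `date`, `doy`,
#'   `year`) with attribute `truth` = list(surface, effort, true_medians,
#'   hotspot_cells).
#' @export
sample_observations <- function(true_medians, effort, surface, years, seed,
                                grid, species = "Synthetica exempli") {
  stopifnot(length(years) >= 1, inherits(effort, "effort_model"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_cells <- nrow(true_medians)
  hot <- if (effort$n_hotspots > 0) {
    sample(true_medians$cell_id, min(effort$n_hotspots, n_cells))
  } else integer(0)
  w <- ifelse(true_medians$cell_id %in% hot, effort$hotspot_multiplier, 1)
  w <- w / mean(w)
  mu <- effort$mean_obs_per_cell * w
  out <- list()
  for (iy in seq_along(years)) {
    med <- true_medians$true_median + surface$year_shift * (iy - 1)
    counts <- switch(effort$count_family,
      poisson = stats::rpois(n_cells, mu),
      negative_binomial = stats::rnbinom(n_cells, size = effort$hotspot_concentration, mu = mu))
    for (i in seq_len(n_cells)) {
      n <- counts[i]
      if (n == 0) next
      d <- switch(surface$shape_family,
        normal = stats::rnorm(n, med[i], surface$dispersion),
        weibull = {
          p <- .weibull_from_median_sd(med[i], surface$dispersion)
          stats::rweibull(n, p$shape, p$scale)
        })
      doy <- pmin(pmax(round(d), 1), 365)
      ctr <- cell_centroids(grid, rep(true_medians$cell_id[i], n))
      px <- ctr$x + stats::runif(n, -0.5, 0.5) * grid$cell_size * 0.999
      py <- ctr$y + stats::runif(n, -0.5, 0.5) * grid$cell_size * 0.999
      geo <- laea_unproject(px, py, grid$crs)
      out[[length(out) + 1L]] <- data.frame(
        species = species, lon = geo$lon, lat = geo$lat,
        date = as.Date(paste0(years[iy], "-01-01")) + doy - 1,
        doy = doy, year = years[iy])
    }
  }
  obs <- if (length(out)) do.call(rbind, out) else {
    data.frame(species = character(), lon = numeric(), lat = numeric(),
               date = as.Date(character()), doy = integer(), year = numeric())
  }
  rownames(obs) <- NULL
  attr(obs, "truth") <- list(surface = surface, effort = effort,
                             true_medians = true_medians,
                             hotspot_cells = hot)
  obs
}

#' Synthetic daily temperature cube
#'
#' `tmean(cell, d) = t_mean_annual + seasonal_amplitude *
#' sin(2*pi*(d - phase_doy)/365 + pi/2) - lapse_rate * elev/1000 -
#' lat_gradient * (lat - min(lat)) + noise`, with the sine phased so the
#' seasonal term peaks at `phase_doy`. `tmin`/`tmax` are `tmean` -/+ half
#' the diurnal range. The year is handled as 365 days (a leap day would be
#' folded into DOY 59).
#'
#' @param covariates data.frame `cell_id`, `elev`, `lat` (and `lon`).
#' @param climate A [synthetic_climate()] object.
#' @param year Year label stored on the cube.
#' @param seed RNG seed for the daily noise.
#' @param n_days Calendar length (365, the package-wide convention).
#' @return A `temperature_cube`: list with `cell_id`, `year`, `n_days`,
#'   matrices `tmin`, `tmax` (cells x days).
#' @export
synth_temperature <- function(covariates, climate, year = 2020, seed = 1,
                              n_days = 365) {
  stopifnot(n_days %in% c(365, 366), inherits(climate, "synthetic_climate"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  d <- seq_len(n_days)
  seas <- climate$seasonal_amplitude * cos(2 * pi * (d - climate$phase_doy) / 365)
  base <- climate$t_mean_annual -
    climate$lapse_rate * covariates$elev / 1000 -
    climate$lat_gradient * (covariates$lat - min(covariates$lat))
  tmean <- outer(base, seas, `+`)
  if (climate$daily_noise_sd > 0) {
    tmean <- tmean + matrix(stats::rnorm(length(tmean), 0, climate$daily_noise_sd),
                            nrow = nrow(tmean))
  }
  structure(list(cell_id = covariates$cell_id, year = year, n_days = n_days,
                 tmin = tmean - climate$diurnal_range / 2,
                 tmax = tmean + climate$diurnal_range / 2),
            class = "temperature_cube")
}

#' @export
print.temperature_cube <- function(x, ...) {
  cat(sprintf("temperature cube: %d cells x %d days, year %s\n",
              length(x$cell_id), x$n_days, x$year))
  invisible(x)
}

#' Observations whose phenology is driven by thermal time
#'
#' Per cell, the true median DOY is the first day on which cumulative
#' growing degree days (base 5 deg C) reach `gdd_threshold`; observation
#' dates are then sampled (normal, sd `dispersion`) around it exactly as in
#' [sample_observations()]. Cells never reaching the threshold produce no
#' observations and are flagged in the `truth` attribute. This couples the
#' generated phenology to the temperature field so the shift-vs-GDD analysis
#' has a known answer.
#'
#' @param temperature A `temperature_cube`.
#' @param gdd_threshold Forcing requirement (deg C days).
#' @param effort An [effort_model()].
#' @param dispersion Observation-date sd (days).
#' @param seed RNG seed.
#' @param grid The `grid_spec` (for coordinates).
#' @param base_temp GDD baseline (deg C, default 5).
#' @param year Year label for the records (default the cube's).
#' @param species Species label.
#' @return Observation data.frame as in [sample_observations()]; `truth`
#'   attribute carries `true_mod` per cell and `unreached_cells`.
#' @export
make_gdd_coupled_observations <- function(temperature, gdd_threshold, effort,
                                          dispersion, seed, grid,
                                          base_temp = 5,
                                          year = temperature$year,
                                          species = "Synthetica thermophila") {
  gdd <- gdd_series(temperature, base_temp = base_temp)
  # threshold 0 degenerates to "first day with any accumulation"
  thr <- max(gdd_threshold, .Machine$double.eps)
  reach <- apply(gdd$gdd, 1, function(g) {
    i <- which(g >= thr)
    if (length(i)) i[1] else NA_integer_
  })
  if (all(is.na(reach))) {
    stop("gdd_threshold ", gdd_threshold, " is never reached in any cell")
  }
  ok <- !is.na(reach)
  tm <- data.frame(cell_id = temperature$cell_id[ok], true_median = reach[ok])
  surf <- true_surface(beta0 = 0, beta_elev = 0, beta_lat = 0, beta_lon = 0,
                       year_shift = 0, dispersion = dispersion,
                       shape_family = "normal")
  obs <- sample_observations(tm, effort, surf, years = year, seed = seed,
                             grid = grid, species = species)
  tr <- attr(obs, "truth")
  tr$true_mod <- tm
  tr$unreached_cells <- temperature$cell_id[!ok]
  tr$gdd_threshold <- gdd_threshold
  attr(obs, "truth") <- tr
  obs
}
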