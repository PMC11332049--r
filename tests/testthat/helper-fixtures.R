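# Shared fixtures built in code: a small deterministic landscape and a
# synthetic cell-covariate table for regression/interpolation tests.

tiny_landscape <- function(n_side = 10, seed = 7) {
  synth_landscape(n_side = n_side, seed = seed)
}

# covariates with a noiseless linear MOD surface attached
linear_mod_grid <- function(cov, b0 = 150, b_elev_km = 20, b_lat = 2,
                            b_lon = 0.5, year = 2020, species = "s",
                            cells = cov$cell_id) {
  cov <- cov[match(cells, cov$cell_id), , drop = FALSE]
  mg <- data.frame(
    species = species, year = year, cell_id = cov$cell_id, n = 30L,
    mod = b0 + b_elev_km * cov$elev / 1000 + b_lat * cov$lat + b_lon * cov$lon,
    mod_naive = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    provenance = "observed")
  class(mg) <- c("mod_grid", "data.frame")
  mg
}

# constant-temperature cube (tmin = tmax = t for every cell and day)
constant_cube <- function(cells, t, n_days = 365, year = 2020) {
  m <- matrix(t, nrow = length(cells), ncol = n_days)
  structure(list(cell_id = cells, year = year, n_days = n_days,
                 tmin = m, tmax = m),
            class = "temperature_cube")
}
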