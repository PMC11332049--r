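# Bioclimatic gradient regression, multiple-testing adjustment, inter-annual
# shift tests, season classification, and the seasonal trend of gradient
# coefficients.

#' Fit the bioclimatic gradient regression for one species x year
#'
#' Ordinary least squares of cell-level MOD on cell mean elevation (m),
#' centroid latitude and longitude (degrees):
#' `mod = m_elev * elev + m_lat * lat + m_lon * lon + n`. Only observed
#' (non-interpolated) cells enter by default: interpolated MODs are
#' functions of the same covariates and would bias the coefficients toward
#' the interpolator. The elevation coefficient is additionally reported per
#' 1000 m, the scale on which elevational phenological shifts are usually
#' quoted.
#'
#' @param mod_grid A `mod_grid` for one species x year.
#' @param covariates data.frame `cell_id`, `elev`, `lat`, `lon`.
#' @param use_interpolated Include interpolated cells (default FALSE).
#' @param holm_adjust_p Adjust the three slope p-values with the
#'   Bonferroni-Holm method (default TRUE; family = the three coefficients
#'   of this model).
#' @return One-row data.frame of class `gradient_fit`: `species`, `year`,
#'   `m_elev` (d/m), `m_elev_per_km` (d/1000 m), `m_lat` (d/deg),
#'   `m_lon` (d/deg), `intercept`, raw and adjusted p-values, `r2`,
#'   `n_cells`, `residual_sd`. The full `lm` fit is attached as attribute
#'   `fit`.
#' @export
fit_gradient_model <- function(mod_grid, covariates, use_interpolated = FALSE,
                               holm_adjust_p = TRUE) {
  mg <- as.data.frame(mod_grid)
  if (!use_interpolated) mg <- mg[mg$provenance == "observed", , drop = FALSE]
  d <- merge(mg[, c("species", "year", "cell_id", "mod")], covariates,
             by = "cell_id")
  if (nrow(d) < 6) {
    stop("need at least 6 cells with MOD to fit the gradient model, have ",
         nrow(d))
  }
  X <- cbind(1, as.matrix(d[, c("elev", "lat", "lon")]))
  if (kappa(scale(X[, -1]), exact = TRUE) > 1e8 || qr(X)$rank < 4) {
    stop("collinear predictors among elev/lat/lon: gradient model is rank deficient")
  }
  fit <- stats::lm(mod ~ elev + lat + lon, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  p_raw <- co[c("elev", "lat", "lon"), "Pr(>|t|)"]
  p_adj <- if (holm_adjust_p) holm_adjust(p_raw) else p_raw
  out <- data.frame(
    species = d$species[1], year = d$year[1],
    m_elev = co["elev", "Estimate"],
    m_elev_per_km = co["elev", "Estimate"] * 1000,
    m_lat = co["lat", "Estimate"], m_lon = co["lon", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    p_elev = unname(p_raw[1]), p_lat = unname(p_raw[2]),
    p_lon = unname(p_raw[3]),
    p_elev_adj = unname(p_adj[1]), p_lat_adj = unname(p_adj[2]),
    p_lon_adj = unname(p_adj[3]),
    r2 = sm$r.squared, n_cells = nrow(d), residual_sd = sm$sigma)
  attr(out, "fit") <- fit
  class(out) <- c("gradient_fit", "data.frame")
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sort ascending, multiply the i-th smallest p by (m - i + 1), enforce
#' monotonicity with a running maximum, cap at 1, return in input order
#' (delegates to [stats::p.adjust()] after validation).
#'
#' @param p_values Numeric p-values in [0, 1].
#' @return Adjusted p-values, same order and length.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' Paired inter-annual test of MOD per species
#'
#' Wilcoxon signed-rank test on per-cell paired MOD differences between two
#' years, per species, two-sided. The difference is year2 - year1; with
#' year1 = 2020 this is the 2021 - 2020 convention, so a positive median
#' shift means earlier flowering in the first year. All-zero differences
#' yield p = 1 with a degenerate flag.
#'
#' @param mod_year1,mod_year2 `mod_grid` tables for the two years.
#' @param min_cells Minimum shared cells per species (default 6).
#' @return data.frame: `species`, `n_cells`, `median_shift` (days,
#'   year2 - year1), `wilcoxon_p`, `degenerate`.
#' @export
paired_mod_test <- function(mod_year1, mod_year2, min_cells = 6) {
  m <- merge(as.data.frame(mod_year1)[, c("species", "cell_id", "mod")],
             as.data.frame(mod_year2)[, c("species", "cell_id", "mod")],
             by = c("species", "cell_id"), suffixes = c("_1", "_2"))
  out <- lapply(split(m, m$species), function(g) {
    if (nrow(g) < min_cells) return(NULL)
    d <- g$mod_2 - g$mod_1
    if (all(d == 0)) {
      return(data.frame(species = g$species[1], n_cells = nrow(g),
                        median_shift = 0, wilcoxon_p = 1, degenerate = TRUE))
    }
    w <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided"))
    data.frame(species = g$species[1], n_cells = nrow(g),
               median_shift = stats::median(d), wilcoxon_p = w$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(species = character(), n_cells = integer(),
                      median_shift = numeric(), wilcoxon_p = numeric(),
                      degenerate = logical())
  }
  rownames(out) <- NULL
  out
}

#' Classify species as spring- or summer-flowering
#'
#' Species whose reference-year median MOD falls strictly before the onset
#' of summer (DOY 172) are spring-flowering; a median MOD at or after that
#' day is summer-flowering.
#'
#' @param species_medians data.frame `species`, `year`, `median_mod` (from
#'   [species_median_mod()]).
#' @param reference_year Year whose medians define the classification.
#' @param threshold_doy Onset of summer (default 172).
#' @return data.frame `species`, `median_mod_reference_year`, `class`,
#'   `threshold_doy`.
#' @export
classify_season <- function(species_medians, reference_year,
                            threshold_doy = 172) {
  d <- species_medians[species_medians$year == reference_year, , drop = FALSE]
  data.frame(
    species = d$species,
    median_mod_reference_year = d$median_mod,
    class = ifelse(d$median_mod < threshold_doy, "spring", "summer"),
    threshold_doy = threshold_doy,
    row.names = NULL)
}

#' Seasonal trend of a gradient coefficient
#'
#' Quadratic OLS of one gradient coefficient (elevational, latitudinal or
#' longitudinal shift) on the species' median MOD, across species x year
#' fits — the hump-shaped relationship of gradient strength over the
#' growing season.
#'
#' @param gradient_fits data.frame of stacked `gradient_fit` rows.
#' @param response One of `"m_elev_per_km"`, `"m_lat"`, `"m_lon"`.
#' @param x Per-point median MOD (same length as `nrow(gradient_fits)`);
#'   defaults to a `median_mod` column if present.
#' @return List of class `seasonal_trend`: `coefficients` (intercept,
#'   linear, quadratic), `vertex_x`, `concavity` (+1/-1), `p_quadratic`,
#'   `r2`, `n`, and the underlying `lm` fit.
#' @export
seasonal_trend <- function(gradient_fits,
                           response = c("m_elev_per_km", "m_lat", "m_lon"),
                           x = gradient_fits$median_mod) {
  response <- match.arg(response)
  y <- gradient_fits[[response]]
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 4) {
    stop("need at least 4 species-year points for the quadratic trend, have ",
         length(y))
  }
  fit <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(fit)
  p_quad <- summary(fit)$coefficients["I(x^2)", "Pr(>|t|)"]
  structure(list(
    response = response,
    coefficients = c(intercept = unname(co[1]), linear = unname(co[2]),
                     quadratic = unname(co[3])),
    vertex_x = if (co[3] != 0) unname(-co[2] / (2 * co[3])) else NA_real_,
    concavity = sign(unname(co[3])),
    p_quadratic = p_quad,
    r2 = summary(fit)$r.squared, n = length(y), fit = fit),
    class = "seasonal_trend")
}

#' @export
print.seasonal_trend <- function(x, ...) {
  cat(sprintf(
    "seasonal trend of %s: vertex at DOY %.1f, concavity %s (p[x^2]=%.3g, n=%d)\n",
    x$response, x$vertex_x, if (x$concavity < 0) "negative (hump)" else "positive",
    x$p_quadratic, x$n))
  invisible(x)
}

#' Per-cell inter-annual MOD shift map
#'
#' Differences two MOD grids over their shared cells with the fixed sign
#' convention delta = year2 - year1 (2021 - 2020 in the two-year study
#' design): positive values mean earlier flowering in year 1.
#'
#' @param mod_year1,mod_year2 `mod_grid` tables.
#' @return data.frame: `species`, `cell_id`, `mod_year1`, `mod_year2`,
#'   `delta_mod`.
#' @export
shift_map <- function(mod_year1, mod_year2) {
  m <- merge(as.data.frame(mod_year1)[, c("species", "cell_id", "mod")],
             as.data.frame(mod_year2)[, c("species", "cell_id", "mod")],
             by = c("species", "cell_id"), suffixes = c("_year1", "_year2"))
  out <- data.frame(species = m$species, cell_id = m$cell_id,
                    mod_year1 = m$mod_year1, mod_year2 = m$mod_year2,
                    delta_mod = m$mod_year2 - m$mod_year1)
  rownames(out) <- NULL
  out
}
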