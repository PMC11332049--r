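# Growing degree days: thermal-time accumulation from daily temperature
# grids, evaluation at the median observation date, and inter-annual shift.

#' Cumulative growing degree days per cell
#'
#' Daily mean = (tmin + tmax) / 2; daily increment = max(0, mean -
#' base_temp); cumulative sum from January 1. The simple averaging GDD
#' formula with the standard base temperature of 5 deg C.
#'
#' @param temps A `temperature_cube` (cells x days `tmin`/`tmax` matrices).
#' @param base_temp Baseline in deg C (default 5).
#' @return A `gdd_cube`: list with `cell_id`, `year`, `n_days`, `base_temp`
#'   and a cells x days matrix `gdd` (non-negative, non-decreasing along
#'   days).
#' @export
gdd_series <- function(temps, base_temp = 5) {
  stopifnot(inherits(temps, "temperature_cube"))
  if (anyNA(temps$tmin) || anyNA(temps$tmax)) {
    gaps <- which(apply(is.na(temps$tmin) | is.na(temps$tmax), 2, any))
    stop("missing temperature days: ", paste(gaps, collapse = ", "))
  }
  if (any(temps$tmax < temps$tmin)) stop("tmax < tmin in temperature cube")
  inc <- (temps$tmin + temps$tmax) / 2 - base_temp
  inc[inc < 0] <- 0
  gdd <- t(apply(inc, 1, cumsum))
  structure(list(cell_id = temps$cell_id, year = temps$year,
                 n_days = temps$n_days, base_temp = base_temp, gdd = gdd),
            class = "gdd_cube")
}

#' @export
print.gdd_cube <- function(x, ...) {
  cat(sprintf("GDD cube: %d cells x %d days, base %g degC, year %s\n",
              length(x$cell_id), x$n_days, x$base_temp, x$year))
  invisible(x)
}

#' Growing degree days accumulated at the median observation date
#'
#' Evaluates the cumulative GDD curve of each cell at that cell's MOD,
#' linearly interpolating between the two bracketing integer days (with
#' GDD(0) = 0, so a MOD before any accumulation evaluates to 0). Cells
#' missing from either input are skipped and reported in the `skipped`
#' attribute.
#'
#' @param gdd A `gdd_cube`.
#' @param mod_grid A `mod_grid` data.frame (only `species`, `year`,
#'   `cell_id`, `mod` are used; the MODs may come from any year — see
#'   [gdd_shift()] for the inter-annual comparison convention).
#' @return data.frame `species`, `year`, `cell_id`, `mod`, `gdd_at_mod`.
#' @export
gdd_at_mod <- function(gdd, mod_grid) {
  stopifnot(inherits(gdd, "gdd_cube"))
  idx <- match(mod_grid$cell_id, gdd$cell_id)
  keep <- !is.na(idx) & is.finite(mod_grid$mod)
  skipped <- mod_grid$cell_id[!keep]
  mg <- mod_grid[keep, , drop = FALSE]
  idx <- idx[keep]
  if (any(mg$mod < 0 | mg$mod > gdd$n_days)) {
    stop("MOD outside the calendar [0, ", gdd$n_days, "]")
  }
  d0 <- floor(mg$mod)
  frac <- mg$mod - d0
  g_at <- function(row, day) ifelse(day < 1, 0, gdd$gdd[cbind(row, pmax(day, 1))])
  g0 <- g_at(idx, d0)
  g1 <- g_at(idx, pmin(d0 + 1, gdd$n_days))
  out <- data.frame(species = mg$species, year = mg$year, cell_id = mg$cell_id,
                    mod = mg$mod, gdd_at_mod = g0 + frac * (g1 - g0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Inter-annual shift in GDD at the median observation date
#'
#' Differences two GDD-at-MOD tables over their shared cells (year b minus
#' year a; with year a = 2020 and b = 2021 this is the 2021 - 2020
#' convention) and summarises per species. When both tables were evaluated
#' at a common reference MOD per cell (see [run_pipeline()]), a warmer year
#' b yields positive median shift while the MOD shift is negative — the
#' complementary-sign relationship between phenological advance and faster
#' thermal accumulation.
#'
#' @param year_a,year_b GDD-at-MOD tables from [gdd_at_mod()].
#' @return List: `per_cell` (data.frame with `delta_gdd` and, when both
#'   tables carry MODs, `delta_mod`) and `summary` (per species median and
#'   IQR of `delta_gdd`).
#' @export
gdd_shift <- function(year_a, year_b) {
  m <- merge(year_a, year_b, by = c("species", "cell_id"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared cells between the two GDD-at-MOD tables")
  per_cell <- data.frame(species = m$species, cell_id = m$cell_id,
                         gdd_a = m$gdd_at_mod_a, gdd_b = m$gdd_at_mod_b,
                         delta_gdd = m$gdd_at_mod_b - m$gdd_at_mod_a,
                         delta_mod = m$mod_b - m$mod_a)
  med <- stats::aggregate(delta_gdd ~ species, data = per_cell, FUN = stats::median)
  iqr <- stats::aggregate(delta_gdd ~ species, data = per_cell, FUN = stats::IQR)
  names(med)[2] <- "median_delta_gdd"
  med$iqr_delta_gdd <- iqr$delta_gdd
  med$n_cells <- stats::aggregate(delta_gdd ~ species, data = per_cell,
                                  FUN = length)$delta_gdd
  list(per_cell = per_cell, summary = med)
}
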