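# Readers and writers: observation CSVs (multi-source pooling), temperature
# cubes as long-format CSV, MOD grids, and sidecar truth metadata for
# synthetic sets.

#' Read presence-only observation records from CSV
#'
#' Parses one observation per row, resolves columns through `column_map`,
#' converts ISO 8601 dates to day-of-year (January 1 = DOY 1) and year, and
#' drops rows with unparseable dates or out-of-range coordinates (counts
#' retained in the `dropped` attribute). Multiple files are pooled into a
#' single set with per-source counts.
#'
#' @param paths One or more CSV paths.
#' @param column_map Named character vector mapping the required fields to
#'   file columns, default
#'   `c(species = "species", lon = "longitude", lat = "latitude", date = "date")`.
#' @param date_format Date format string (default ISO 8601, `%Y-%m-%d`).
#' @return Observation data.frame (`species`, `lon`, `lat`, `date`, `doy`,
#'   `year`); attributes `dropped` (named counts) and `per_source` (rows
#'   retained per file).
#' @export
read_observations <- function(paths,
                              column_map = c(species = "species",
                                             lon = "longitude",
                                             lat = "latitude",
                                             date = "date"),
                              date_format = "%Y-%m-%d") {
  stopifnot(all(c("species", "lon", "lat", "date") %in% names(column_map)))
  per_source <- integer(length(paths))
  dropped <- c(bad_date = 0L, bad_coord = 0L)
  parts <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    raw <- utils::read.csv(paths[i], stringsAsFactors = FALSE)
    miss <- setdiff(unname(column_map), names(raw))
    if (length(miss)) {
      stop("file ", paths[i], " lacks required column(s): ",
           paste(miss, collapse = ", "))
    }
    d <- data.frame(species = as.character(raw[[column_map[["species"]]]]),
                    lon = as.numeric(raw[[column_map[["lon"]]]]),
                    lat = as.numeric(raw[[column_map[["lat"]]]]),
                    date = as.Date(as.character(raw[[column_map[["date"]]]]),
                                   format = date_format))
    ok_date <- !is.na(d$date)
    ok_coord <- is.finite(d$lon) & is.finite(d$lat) &
      d$lon >= -180 & d$lon <= 180 & d$lat >= -90 & d$lat <= 90
    dropped["bad_date"] <- dropped["bad_date"] + sum(!ok_date)
    dropped["bad_coord"] <- dropped["bad_coord"] + sum(ok_date & !ok_coord)
    d <- d[ok_date & ok_coord, , drop = FALSE]
    lt <- as.POSIXlt(d$date)
    d$doy <- lt$yday + 1L
    d$year <- lt$year + 1900L
    per_source[i] <- nrow(d)
    parts[[i]] <- d
  }
  obs <- do.call(rbind, parts)
  rownames(obs) <- NULL
  attr(obs, "dropped") <- dropped
  attr(obs, "per_source") <- stats::setNames(per_source, paths)
  obs
}

#' Write an observation set as CSV (plus optional truth sidecar)
#'
#' Columns `species`, `longitude`, `latitude`, `date` (ISO 8601). If the
#' set carries synthetic `truth` metadata, it is written alongside as JSON.
#'
#' @param observations Observation data.frame.
#' @param path Output CSV path.
#' @param truth_path Optional path for the sidecar JSON of generating
#'   parameters (default: `path` with `.truth.json` appended when truth is
#'   present).
#' @return Invisibly, the paths written.
#' @export
write_observations <- function(observations, path, truth_path = NULL) {
  utils::write.csv(
    data.frame(species = observations$species,
               longitude = observations$lon,
               latitude = observations$lat,
               date = format(observations$date, "%Y-%m-%d")),
    path, row.names = FALSE)
  written <- path
  truth <- attr(observations, "truth")
  if (!is.null(truth)) {
    if (is.null(truth_path)) truth_path <- paste0(path, ".truth.json")
    jsonlite::write_json(
      lapply(truth, function(x) if (is.data.frame(x)) x else unclass(x)),
      truth_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, truth_path)
  }
  invisible(written)
}

#' Write a temperature cube as long-format CSV
#'
#' One row per cell x day: `cell_id`, `year`, `day`, `tmin`, `tmax`.
#'
#' @param cube A `temperature_cube`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_temperature_csv <- function(cube, path) {
  stopifnot(inherits(cube, "temperature_cube"))
  long <- data.frame(
    cell_id = rep(cube$cell_id, times = cube$n_days),
    year = cube$year,
    day = rep(seq_len(cube$n_days), each = length(cube$cell_id)),
    tmin = as.vector(cube$tmin),
    tmax = as.vector(cube$tmax))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a temperature cube from long-format CSV
#'
#' Expects the format written by [write_temperature_csv()] and validates
#' completeness: every cell must have every day of the year.
#'
#' @param path CSV path.
#' @return A `temperature_cube`.
#' @export
read_temperature_csv <- function(path) {
  long <- utils::read.csv(path)
  need <- c("cell_id", "year", "day", "tmin", "tmax")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("temperature CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  cells <- sort(unique(long$cell_id))
  n_days <- max(long$day)
  if (!n_days %in% c(365, 366)) stop("calendar length must be 365 or 366 days")
  full <- expand.grid(day = seq_len(n_days), cell_id = cells)
  have <- paste(long$cell_id, long$day)
  gaps <- full[!paste(full$cell_id, full$day) %in% have, , drop = FALSE]
  if (nrow(gaps)) {
    stop("temperature CSV has gaps, e.g. cell ", gaps$cell_id[1], " day ",
         gaps$day[1], " (", nrow(gaps), " missing cell-days)")
  }
  o <- order(long$day, long$cell_id)
  long <- long[o, ]
  structure(list(cell_id = cells, year = long$year[1], n_days = n_days,
                 tmin = matrix(long$tmin, nrow = length(cells)),
                 tmax = matrix(long$tmax, nrow = length(cells))),
            class = "temperature_cube")
}

#' Re-scale a pixel-level temperature field to the analysis grid
#'
#' Aggregates a long-format pixel table (`lon`, `lat`, `day`, `tmin`,
#' `tmax`) to per-cell daily means over the pixels intersecting each cell —
#' the unweighted block mean used throughout for re-scaling source grids to
#' the 50 km analysis grid.
#'
#' @param pixels data.frame `lon`, `lat`, `day`, `tmin`, `tmax`.
#' @param grid A `grid_spec`.
#' @param year Year label for the cube.
#' @param cells Cells that must be covered (default: all cells receiving at
#'   least one pixel).
#' @return A `temperature_cube` over `cells`.
#' @export
rescale_temperature <- function(pixels, grid, year, cells = NULL) {
  p <- laea_project(pixels$lon, pixels$lat, grid$crs)
  id <- cell_id_at(p$x, p$y, grid)
  ok <- !is.na(id)
  px <- pixels[ok, , drop = FALSE]
  id <- id[ok]
  covered <- sort(unique(id))
  if (is.null(cells)) cells <- covered
  missing <- setdiff(cells, covered)
  if (length(missing)) {
    stop("no temperature pixels intersect cell(s): ",
         paste(missing, collapse = ", "))
  }
  n_days <- max(px$day)
  keep <- id %in% cells
  px <- px[keep, , drop = FALSE]; id <- id[keep]
  key <- factor(id, levels = cells)
  tmin <- tapply(px$tmin, list(key, factor(px$day, levels = seq_len(n_days))), mean)
  tmax <- tapply(px$tmax, list(key, factor(px$day, levels = seq_len(n_days))), mean)
  if (anyNA(tmin) || anyNA(tmax)) {
    stop("temperature pixels do not cover every day for every cell")
  }
  structure(list(cell_id = cells, year = year, n_days = n_days,
                 tmin = unname(as.matrix(tmin)), tmax = unname(as.matrix(tmax))),
            class = "temperature_cube")
}

#' Write a MOD grid as CSV
#'
#' @param mod_grid A `mod_grid`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mod_grid <- function(mod_grid, path) {
  utils::write.csv(as.data.frame(mod_grid), path, row.names = FALSE)
  invisible(path)
}
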