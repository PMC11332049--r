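# Equal-area gridding: project observations onto a 50 x 50 km raster,
# aggregate per species x year x cell, attach per-cell covariates.

#' Construct an equal-area analysis grid
#'
#' Builds a regular grid of square cells in the projected equal-area plane
#' that fully covers a geographic bounding box. The origin sits at the
#' projected minimum of the (densified) bbox outline, so a bbox that fits in
#' one cell yields a 1 x 1 grid; use [grid_spec()] directly to align a grid
#' to an external reference. Cells use half-open intervals
#' `[x, x + cell_size)` so every point belongs to exactly one cell, and are
#' indexed row-major from the lower-left origin (cell_id 1 = SW corner).
#'
#' @param bbox Named numeric vector `c(lon_min, lat_min, lon_max, lat_max)`
#'   in decimal degrees.
#' @param cell_size Cell edge length in metres (default 50 km).
#' @param crs A [laea_crs()] object.
#' @return A `grid_spec` list: `crs`, `origin_x`, `origin_y`, `cell_size`,
#'   `n_cols`, `n_rows`.
#' @export
build_grid <- function(bbox, cell_size = 50000, crs = laea_crs()) {
  stopifnot(length(bbox) == 4, cell_size > 0)
  lon_min <- bbox[[1]]; lat_min <- bbox[[2]]
  lon_max <- bbox[[3]]; lat_max <- bbox[[4]]
  if (!(lon_max > lon_min) || !(lat_max > lat_min)) {
    stop("degenerate bounding box: require lon_max > lon_min and lat_max > lat_min")
  }
  # densify the bbox outline: a geographic rectangle maps to a curved region
  s <- seq(0, 1, length.out = 101)
  edge_lon <- c(lon_min + s * (lon_max - lon_min), rep(lon_max, 101),
                lon_max - s * (lon_max - lon_min), rep(lon_min, 101))
  edge_lat <- c(rep(lat_min, 101), lat_min + s * (lat_max - lat_min),
                rep(lat_max, 101), lat_max - s * (lat_max - lat_min))
  p <- laea_project(edge_lon, edge_lat, crs)
  origin_x <- min(p$x)
  origin_y <- min(p$y)
  structure(
    list(crs = crs, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size,
         n_cols = ceiling((max(p$x) - origin_x) / cell_size),
         n_rows = ceiling((max(p$y) - origin_y) / cell_size)),
    class = "grid_spec"
  )
}

#' Construct a grid directly from projected-plane parameters
#'
#' Lower-level companion of [build_grid()] used by the synthetic-data
#' generator, where the landscape is laid out in the projected plane.
#'
#' @param origin_x,origin_y Lower-left corner in metres.
#' @param n_cols,n_rows Grid dimensions.
#' @inheritParams build_grid
#' @return A `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, n_cols, n_rows,
                      cell_size = 50000, crs = laea_crs()) {
  stopifnot(cell_size > 0, n_cols >= 1, n_rows >= 1)
  structure(
    list(crs = crs, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, n_cols = n_cols, n_rows = n_rows),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("equal-area grid: %d x %d cells of %.0f m (%s)\n",
              x$n_cols, x$n_rows, x$cell_size, x$crs$name))
  invisible(x)
}

#' Map projected coordinates to cell ids
#'
#' Half-open assignment: a point on a shared edge belongs to the cell on its
#' upper-right side in index terms (i.e. the lower/left cell owns its lower
#' and left edges). Points outside the grid get `NA`.
#'
#' @param x,y Projected coordinates (metres).
#' @param grid A `grid_spec`.
#' @return Integer cell ids (row-major, 1-based) or `NA`.
#' @export
cell_id_at <- function(x, y, grid) {
  col <- floor((x - grid$origin_x) / grid$cell_size)
  row <- floor((y - grid$origin_y) / grid$cell_size)
  ok <- col >= 0 & col < grid$n_cols & row >= 0 & row < grid$n_rows
  id <- as.integer(row * grid$n_cols + col + 1)
  id[!ok] <- NA_integer_
  id
}

#' Projected centroids of grid cells
#'
#' @param grid A `grid_spec`.
#' @param cell_ids Cells to return (default all).
#' @return data.frame `cell_id`, `x`, `y` (projected centre, metres).
#' @export
cell_centroids <- function(grid, cell_ids = seq_len(grid$n_cols * grid$n_rows)) {
  cell_ids <- as.integer(cell_ids)
  stopifnot(all(cell_ids >= 1), all(cell_ids <= grid$n_cols * grid$n_rows))
  col <- (cell_ids - 1L) %% grid$n_cols
  row <- (cell_ids - 1L) %/% grid$n_cols
  data.frame(
    cell_id = cell_ids,
    x = grid$origin_x + (col + 0.5) * grid$cell_size,
    y = grid$origin_y + (row + 0.5) * grid$cell_size
  )
}

#' Assign observations to cells and aggregate per species x year x cell
#'
#' Projects observation coordinates, assigns each to exactly one grid cell
#' (half-open rule), and collects day-of-year samples per species, year and
#' cell. Samples below `min_count` are excluded from estimation but reported
#' in the coverage summary, following the minimum-observation filter used to
#' stabilise the percentile estimates.
#'
#' @param observations An observation data.frame as returned by
#'   [read_observations()] or [sample_observations()]: columns `species`,
#'   `lon`, `lat`, `doy`, `year`.
#' @param grid A `grid_spec`.
#' @param min_count Minimum observations per cell sample (default 25).
#' @return A list of class `cell_samples`: `samples` (list of
#'   species/year/cell_id/doys/n), `coverage` (data.frame with per-group
#'   counts and a `retained` flag), and `counts` (input / assigned /
#'   outside-grid / retained / sub-threshold totals).
#' @export
assign_and_aggregate <- function(observations, grid, min_count = 25) {
  stopifnot(min_count >= 1)
  req <- c("species", "lon", "lat", "doy", "year")
  miss <- setdiff(req, names(observations))
  if (length(miss)) stop("observations lack columns: ", paste(miss, collapse = ", "))
  n_in <- nrow(observations)
  if (n_in == 0) {
    return(structure(list(samples = list(),
                          coverage = data.frame(),
                          counts = c(input = 0, assigned = 0, outside = 0,
                                     retained = 0, sub_threshold = 0)),
                     class = "cell_samples"))
  }
  p <- laea_project(observations$lon, observations$lat, grid$crs)
  id <- cell_id_at(p$x, p$y, grid)
  inside <- !is.na(id)
  obs <- observations[inside, , drop = FALSE]
  id <- id[inside]
  key <- interaction(obs$species, obs$year, id, drop = TRUE)
  groups <- split(seq_len(nrow(obs)), key)
  samples <- lapply(groups, function(ix) {
    list(species = obs$species[ix[1]], year = obs$year[ix[1]],
         cell_id = id[ix[1]], doys = obs$doy[ix], n = length(ix))
  })
  names(samples) <- NULL
  n_per <- vapply(samples, `[[`, integer(1), "n")
  coverage <- data.frame(
    species = vapply(samples, `[[`, character(1), "species"),
    year = vapply(samples, `[[`, numeric(1), "year"),
    cell_id = vapply(samples, `[[`, integer(1), "cell_id"),
    n = n_per,
    retained = n_per >= min_count
  )
  structure(
    list(samples = samples[coverage$retained],
         coverage = coverage,
         counts = c(input = n_in, assigned = nrow(obs),
                    outside = n_in - nrow(obs),
                    retained = sum(n_per[n_per >= min_count]),
                    sub_threshold = sum(n_per[n_per < min_count]))),
    class = "cell_samples"
  )
}

#' @export
print.cell_samples <- function(x, ...) {
  cat(sprintf("cell samples: %d retained groups (min-count filter), counts: %s\n",
              length(x$samples),
              paste(names(x$counts), x$counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' Per-cell covariates: mean elevation and geographic centroid
#'
#' Aggregates a point/pixel elevation field to the analysis grid (unweighted
#' mean of pixels falling in each cell) and attaches the geographic
#' coordinates of each projected cell centroid — the predictors of the
#' bioclimatic gradient regression.
#'
#' @param grid A `grid_spec`.
#' @param elevation_grid data.frame with columns `lon`, `lat`, `elev`
#'   (pixel centres, metres).
#' @param retained_cells Cell ids that must receive a value.
#' @return data.frame `cell_id`, `elev`, `lat`, `lon`.
#' @export
cell_covariates <- function(grid, elevation_grid, retained_cells) {
  stopifnot(all(c("lon", "lat", "elev") %in% names(elevation_grid)))
  retained_cells <- as.integer(retained_cells)
  p <- laea_project(elevation_grid$lon, elevation_grid$lat, grid$crs)
  id <- cell_id_at(p$x, p$y, grid)
  ok <- !is.na(id)
  means <- tapply(elevation_grid$elev[ok], id[ok], mean)
  missing <- setdiff(retained_cells, as.integer(names(means)))
  if (length(missing)) {
    stop("no elevation pixels intersect cell(s): ", paste(missing, collapse = ", "))
  }
  ctr <- cell_centroids(grid, retained_cells)
  geo <- laea_unproject(ctr$x, ctr$y, grid$crs)
  data.frame(
    cell_id = retained_cells,
    elev = as.numeric(means[as.character(retained_cells)]),
    lat = geo$lat,
    lon = geo$lon
  )
}
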