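# End-to-end orchestration: grid -> aggregate -> MOD -> interpolate (AOA)
# -> GDD -> gradients / shifts / tests, with a machine-readable manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default; the whole
#' object is echoed into the run manifest so no default stays silent.
#'
#' @param cell_size Grid cell edge in metres (default 50 km).
#' @param crs A [laea_crs()].
#' @param min_count Minimum observations per cell sample (default 25; the
#'   more permissive mapping threshold of 20 is available by setting it).
#' @param q Percentile estimated (default 0.5, the MOD).
#' @param n_bootstrap Bootstrap replicates per cell (default 250).
#' @param seed Base RNG seed.
#' @param interpolate Enable SVR interpolation inside the AOA.
#' @param base_temp GDD baseline (deg C).
#' @param gdd_eval `"reference"` evaluates both years' GDD at the first
#'   year's per-cell MOD (the inter-annual comparison default);
#'   `"own_year"` evaluates each year at its own MOD.
#' @param use_interpolated_in_regression Feed interpolated cells to the
#'   gradient regression (default FALSE).
#' @param season_threshold_doy Spring/summer split (default 172).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_size = 50000, crs = laea_crs(),
                            min_count = 25, q = 0.5, n_bootstrap = 250,
                            seed = 1, interpolate = TRUE, base_temp = 5,
                            gdd_eval = c("reference", "own_year"),
                            use_interpolated_in_regression = FALSE,
                            season_threshold_doy = 172) {
  gdd_eval <- match.arg(gdd_eval)
  structure(list(cell_size = cell_size, crs = crs, min_count = min_count,
                 q = q, n_bootstrap = n_bootstrap, seed = seed,
                 interpolate = interpolate, base_temp = base_temp,
                 gdd_eval = gdd_eval,
                 use_interpolated_in_regression = use_interpolated_in_regression,
                 season_threshold_doy = season_threshold_doy),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains all stages for a two-year (or multi-year) observation set:
#' aggregation on the equal-area grid, per-cell MOD estimation,
#' SVR interpolation inside the area of applicability, growing degree
#' days, gradient regressions per species x year, inter-annual shift maps
#' and paired tests, season classification, and the seasonal trend of
#' gradient coefficients. All randomness derives from `config$seed`.
#'
#' @param observations Observation data.frame (`species`, `lon`, `lat`,
#'   `doy`, `year`).
#' @param grid A `grid_spec`.
#' @param covariates data.frame `cell_id`, `elev`, `lat`, `lon` (all cells
#'   eligible for estimation or interpolation).
#' @param temperature Optional named list of `temperature_cube`s, one per
#'   year (names = year labels); enables the GDD stage.
#' @param config A [pipeline_config()].
#' @return A list of class `pheno_result`: `cell_samples`, `mod_observed`,
#'   `mod_filled`, `aoa`, `gradient_fits`, `species_medians`, `season`,
#'   `shifts`, `wilcoxon`, `gdd_shift`, `trend_elev`, and `manifest`.
#' @export
run_pipeline <- function(observations, grid, covariates, temperature = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "aggregate"
  res <- list()
  tryCatch({
    cs <- assign_and_aggregate(observations, grid, min_count = config$min_count)
    res$cell_samples <- cs

    stage <- "estimate"
    mod <- mod_table(cs, q = config$q, n_bootstrap = config$n_bootstrap,
                     seed = config$seed, min_count = config$min_count)
    res$mod_observed <- mod

    stage <- "interpolate"
    groups <- split(seq_len(nrow(mod)),
                    interaction(mod$species, mod$year, drop = TRUE))
    filled <- list(); aoa_list <- list()
    for (g in groups) {
      mg <- mod[g, , drop = FALSE]
      class(mg) <- c("mod_grid", "data.frame")
      if (config$interpolate && nrow(mg) >= 10) {
        model <- train_interpolator(mg, covariates)
        aoa <- area_of_applicability(model, covariates)
        mg <- fill_grid(mg, model, aoa, covariates)
        aoa_list[[length(aoa_list) + 1L]] <-
          cbind(species = mg$species[1], year = mg$year[1],
                as.data.frame(aoa))
      }
      filled[[length(filled) + 1L]] <- as.data.frame(mg)
    }
    mod_filled <- do.call(rbind, filled)
    rownames(mod_filled) <- NULL
    class(mod_filled) <- c("mod_grid", "data.frame")
    res$mod_filled <- mod_filled
    res$aoa <- if (length(aoa_list)) do.call(rbind, aoa_list) else NULL

    stage <- "inference"
    reg_grid <- if (config$use_interpolated_in_regression) mod_filled else mod
    fits <- lapply(split(seq_len(nrow(reg_grid)),
                         interaction(reg_grid$species, reg_grid$year, drop = TRUE)),
                   function(ix) {
      mg <- reg_grid[ix, , drop = FALSE]
      class(mg) <- c("mod_grid", "data.frame")
      tryCatch(fit_gradient_model(
        mg, covariates,
        use_interpolated = config$use_interpolated_in_regression),
        error = function(e) NULL)
    })
    fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
    if (!is.null(fits)) rownames(fits) <- NULL
    res$gradient_fits <- fits
    res$species_medians <- species_median_mod(mod)

    years <- sort(unique(mod$year))
    if (length(years) >= 2) {
      y1 <- mod[mod$year == years[1], , drop = FALSE]
      y2 <- mod[mod$year == years[2], , drop = FALSE]
      res$shifts <- shift_map(y1, y2)
      res$wilcoxon <- paired_mod_test(y1, y2)
      res$season <- classify_season(res$species_medians, reference_year = years[1],
                                    threshold_doy = config$season_threshold_doy)
      if (!is.null(fits) && !is.null(res$species_medians) && nrow(fits) >= 4) {
        fits_x <- merge(fits, res$species_medians[, c("species", "year", "median_mod")],
                        by = c("species", "year"))
        res$trend_elev <- tryCatch(
          seasonal_trend(fits_x, "m_elev_per_km", x = fits_x$median_mod),
          error = function(e) NULL)
      }
    }

    stage <- "gdd"
    if (!is.null(temperature) && length(years) >= 2) {
      ylab <- as.character(years)
      if (all(ylab %in% names(temperature))) {
        g1 <- gdd_series(temperature[[ylab[1]]], base_temp = config$base_temp)
        g2 <- gdd_series(temperature[[ylab[2]]], base_temp = config$base_temp)
        y1 <- mod[mod$year == years[1], , drop = FALSE]
        y2 <- mod[mod$year == years[2], , drop = FALSE]
        eval2 <- if (config$gdd_eval == "reference") y1 else y2
        res$gdd_at_mod_year1 <- gdd_at_mod(g1, y1)
        res$gdd_at_mod_year2 <- gdd_at_mod(g2, eval2)
        res$gdd_shift <- gdd_shift(res$gdd_at_mod_year1, res$gdd_at_mod_year2)
      }
    }
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  res$manifest <- list(
    package = "phenoshift",
    version = as.character(utils::packageVersion("phenoshift")),
    config = unclass(config)[setdiff(names(config), "crs")],
    crs = unclass(config$crs),
    seed = config$seed,
    counts = as.list(res$cell_samples$counts),
    n_estimated = nrow(res$mod_observed),
    n_interpolated = if (!is.null(res$mod_filled))
      sum(res$mod_filled$provenance == "interpolated") else 0L)
  class(res) <- "pheno_result"
  res
}

#' @export
print.pheno_result <- function(x, ...) {
  m <- x$manifest
  cat("phenology pipeline result\n")
  cat(sprintf("  observations: %s assigned, %s retained after min-count filter\n",
              m$counts$assigned, m$counts$retained))
  cat(sprintf("  cells estimated: %d (+%d interpolated)\n",
              m$n_estimated, m$n_interpolated))
  if (!is.null(x$gradient_fits)) {
    cat(sprintf("  gradient fits: %d species-year models\n",
                nrow(x$gradient_fits)))
  }
  if (!is.null(x$wilcoxon) && nrow(x$wilcoxon)) {
    cat(sprintf("  median inter-annual shift (year2-year1): %.2f d (p=%.3g)\n",
                x$wilcoxon$median_shift[1], x$wilcoxon$wilcoxon_p[1]))
  }
  invisible(x)
}

#' Write all pipeline outputs and the run manifest
#'
#' @param result A `pheno_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(obj, name) {
    if (is.null(obj) || (is.data.frame(obj) && nrow(obj) == 0)) return()
    f <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(result$mod_filled, "mod_grid.csv")
  wr(result$gradient_fits, "gradient_fits.csv")
  wr(result$shifts, "shift_map.csv")
  wr(result$wilcoxon, "wilcoxon_tests.csv")
  wr(result$season, "season_classes.csv")
  wr(result$aoa, "aoa_report.csv")
  if (!is.null(result$gdd_shift)) wr(result$gdd_shift$per_cell, "gdd_shift.csv")
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(result$manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}
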