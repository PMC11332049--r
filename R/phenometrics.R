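# Median observation date (MOD): bias-corrected Weibull 50th percentile with
# parametric-bootstrap confidence intervals, estimated per species x year x
# grid cell.

#' Maximum-likelihood fit of a two-parameter Weibull distribution
#'
#' Fits shape and scale by maximising the likelihood via the profiled score
#' equation: for fixed shape k the MLE of scale is `mean(x^k)^(1/k)`, leaving
#' a one-dimensional root-find in k. This keeps the fit fast enough to be
#' called hundreds of times per cell inside the parametric bootstrap. The
#' root is solved in log-shape space; the shape estimate is invariant to
#' rescaling of the data, which is exploited for numerical stability.
#'
#' @param doys Numeric vector of (positive) day-of-year values, `n >= 2`,
#'   not all identical.
#' @param location Fixed location offset subtracted before fitting
#'   (default 0, i.e. a two-parameter Weibull on raw DOY).
#' @return A list of class `weibull_params`: `shape`, `scale`, `location`,
#'   `n`, `loglik`.
#' @export
fit_weibull <- function(doys, location = 0) {
  x <- as.numeric(doys) - location
  if (length(x) < 2) stop("need at least 2 observations to fit a Weibull")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all values must be finite and greater than the location offset")
  }
  if (length(unique(x)) == 1L) {
    stop("all values identical: degenerate sample, no Weibull fit ",
         "(handled upstream by estimate_percentile)")
  }
  z <- x / max(x)                       # shape is scale-invariant
  lz <- log(z)
  mlz <- mean(lz)
  score <- function(u) {
    k <- exp(u)
    zk <- z^k
    1 / k + mlz - sum(zk * lz) / sum(zk)
  }
  lo <- log(1e-3); hi <- log(1e5)
  if (score(lo) <= 0 || score(hi) >= 0) stop("Weibull MLE did not converge: score not bracketed")
  u <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  shape <- exp(u)
  scale <- max(x) * mean(z^shape)^(1 / shape)
  ll <- sum(stats::dweibull(x, shape, scale, log = TRUE))
  if (!is.finite(ll)) stop("Weibull MLE did not converge: non-finite log-likelihood")
  structure(list(shape = shape, scale = scale, location = location,
                 n = length(x), loglik = ll),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull fit: shape=%.4g scale=%.4g location=%g (n=%d, logLik=%.2f)\n",
              x$shape, x$scale, x$location, x$n, x$loglik))
  invisible(x)
}

#' Closed-form Weibull quantile
#'
#' `location + scale * (-log(1 - q))^(1/shape)`.
#'
#' @param params A `weibull_params` object (or list with `shape`, `scale`,
#'   optional `location`).
#' @param q Probability strictly inside (0, 1); vectorised.
#' @return Quantile(s) on the day-of-year scale.
#' @export
weibull_quantile <- function(params, q) {
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  loc <- if (is.null(params$location)) 0 else params$location
  loc + params$scale * (-log(1 - q))^(1 / params$shape)
}

#' Bias-corrected Weibull percentile with bootstrap confidence interval
#'
#' The naive estimate is the fitted-Weibull quantile at `q`. A parametric
#' bootstrap then draws `n_bootstrap` samples of size `n` from the fitted
#' distribution, recomputes the naive estimator on each, and subtracts the
#' mean bootstrap bias from the naive estimate (one-step bias correction).
#' The confidence interval is the 2.5/97.5 percentile range of the bootstrap
#' estimates re-centred on the corrected estimate. Integer day-of-year ties
#' are jittered uniformly within +/- 0.5 day before maximum-likelihood
#' fitting (continuous MLE on rounded calendar dates); jitter and bootstrap
#' share the seed, so results are reproducible.
#'
#' @param doys Day-of-year sample for one species x year x cell.
#' @param q Percentile as a fraction (default 0.5, the median observation
#'   date).
#' @param n_bootstrap Bootstrap replicates (default 250, minimum 100).
#' @param seed Integer RNG seed.
#' @param min_count Minimum sample size accepted (default 25); smaller
#'   samples are refused so the cell can be interpolated instead.
#' @param conf_level Confidence level for the percentile interval.
#' @return A list of class `pheno_estimate`: `q`, `mod` (corrected),
#'   `mod_naive`, `ci_low`, `ci_high`, `n`, `n_bootstrap`, `method_tag`
#'   (`"bias_corrected"`, or `"degenerate"` when all observations share one
#'   day), and the fitted `params`.
#' @export
estimate_percentile <- function(doys, q = 0.5, n_bootstrap = 250, seed = 1,
                                min_count = 25, conf_level = 0.95) {
  n <- length(doys)
  if (n < min_count) {
    stop(sprintf(
      "refusing to estimate percentile from n=%d < min_count=%d observations; interpolate this cell instead",
      n, min_count))
  }
  if (n_bootstrap < 100) stop("n_bootstrap must be at least 100")
  if (length(unique(doys)) == 1L) {
    v <- as.numeric(doys[1])
    return(structure(list(q = q, mod = v, mod_naive = v, ci_low = v,
                          ci_high = v, n = n, n_bootstrap = 0L,
                          method_tag = "degenerate", params = NULL),
                     class = "pheno_estimate"))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  x <- as.numeric(doys)
  if (anyDuplicated(x)) x <- x + stats::runif(n, -0.5, 0.5)
  fit <- fit_weibull(x)
  naive <- weibull_quantile(fit, q)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    xb <- stats::rweibull(n, fit$shape, fit$scale)
    weibull_quantile(fit_weibull(xb), q)
  }, numeric(1))
  corrected <- naive - (mean(boot) - naive)    # = 2*naive - mean(boot)
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha))) - mean(boot) + corrected
  structure(list(q = q, mod = corrected, mod_naive = naive,
                 ci_low = min(ci[1], corrected), ci_high = max(ci[2], corrected),
                 n = n, n_bootstrap = as.integer(n_bootstrap),
                 method_tag = "bias_corrected", params = fit),
            class = "pheno_estimate")
}

#' @export
print.pheno_estimate <- function(x, ...) {
  cat(sprintf("percentile q=%.2f: %.2f [%.2f, %.2f] (naive %.2f, n=%d, %s)\n",
              x$q, x$mod, x$ci_low, x$ci_high, x$mod_naive, x$n, x$method_tag))
  invisible(x)
}

#' MOD table: percentile estimates for every retained cell sample
#'
#' Runs [estimate_percentile()] over the retained samples of
#' [assign_and_aggregate()] output and assembles the per-cell MOD surface.
#' Each sample gets a seed derived deterministically from `seed` and its
#' position, so the whole table is reproducible. Estimation failures are
#' collected, not fatal.
#'
#' @param samples A `cell_samples` object (or plain list of samples).
#' @param q Percentile (default 0.5).
#' @param n_bootstrap Bootstrap replicates per cell.
#' @param seed Base RNG seed.
#' @param min_count Minimum observations per sample.
#' @return A data.frame of class `mod_grid`: `species`, `year`, `cell_id`,
#'   `n`, `mod`, `mod_naive`, `ci_low`, `ci_high`, `provenance`
#'   (`"observed"`). Attributes: `failures` (data.frame of cell failures and
#'   reasons), `species_median` (per species x year median over cell MODs,
#'   used for ordering and season classification).
#' @export
mod_table <- function(samples, q = 0.5, n_bootstrap = 250, seed = 1,
                      min_count = 25) {
  slist <- if (inherits(samples, "cell_samples")) samples$samples else samples
  rows <- vector("list", length(slist))
  fails <- list()
  for (i in seq_along(slist)) {
    s <- slist[[i]]
    est <- tryCatch(
      estimate_percentile(s$doys, q = q, n_bootstrap = n_bootstrap,
                          seed = seed + i, min_count = min_count),
      error = function(e) e)
    if (inherits(est, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        species = s$species, year = s$year, cell_id = s$cell_id,
        reason = conditionMessage(est))
      next
    }
    rows[[i]] <- data.frame(
      species = s$species, year = s$year, cell_id = s$cell_id, n = s$n,
      mod = est$mod, mod_naive = est$mod_naive,
      ci_low = est$ci_low, ci_high = est$ci_high,
      provenance = "observed")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(species = character(), year = numeric(),
                      cell_id = integer(), n = integer(), mod = numeric(),
                      mod_naive = numeric(), ci_low = numeric(),
                      ci_high = numeric(), provenance = character())
  }
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else NULL
  attr(out, "species_median") <- species_median_mod(out)
  class(out) <- c("mod_grid", "data.frame")
  out
}

#' Per-species median of cell MODs
#'
#' The species-level summary phenometric: the median over all cell-level
#' MODs for one species and year. Used to order species within the season
#' and to classify spring- vs summer-flowering.
#'
#' @param mod_grid A `mod_grid` data.frame.
#' @return data.frame `species`, `year`, `median_mod`, `n_cells`.
#' @export
species_median_mod <- function(mod_grid) {
  if (nrow(mod_grid) == 0) {
    return(data.frame(species = character(), year = numeric(),
                      median_mod = numeric(), n_cells = integer()))
  }
  agg <- stats::aggregate(mod ~ species + year, data = mod_grid, FUN = stats::median)
  cnt <- stats::aggregate(mod ~ species + year, data = mod_grid, FUN = length)
  names(agg)[3] <- "median_mod"
  agg$n_cells <- cnt$mod
  agg[order(agg$species, agg$year), , drop = FALSE]
}

# save/restore global RNG state so seeded helpers do not disturb callers
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
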