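# Spatial interpolation of MOD for under-sampled cells: RBF support-vector
# regression on (elevation, latitude, longitude), restricted to the area of
# applicability (AOA) of the trained model.

#' Train the MOD interpolator
#'
#' Support-vector eps-regression (radial basis kernel) of cell MOD on
#' standardized elevation, latitude and longitude, trained on the observed
#' cells of one species x year. Hyperparameters are selected by k-fold
#' cross-validation over a small fixed grid with deterministic fold
#' assignment (cell order modulo k), so training is fully reproducible.
#'
#' @param mod_grid Observed `mod_grid` rows for one species x year.
#' @param covariates data.frame `cell_id`, `elev`, `lat`, `lon`.
#' @param cost,gamma,epsilon Candidate hyperparameter values for the CV grid.
#' @param folds Number of CV folds (default 5).
#' @return A list of class `interpolation_model`: the fitted `svm`, the
#'   predictor standardization (`center`, `scale`), the standardized
#'   training matrix, `cell_ids`, chosen hyperparameters, `cv_rmse` and
#'   training `r2`.
#' @export
train_interpolator <- function(mod_grid, covariates,
                               cost = c(1, 10, 100, 1000),
                               gamma = c(0.01, 0.1, 1),
                               epsilon = 0.1, folds = 5) {
  d <- merge(as.data.frame(mod_grid)[, c("cell_id", "mod")], covariates,
             by = "cell_id")
  if (nrow(d) < 10) {
    stop("interpolation skipped: only ", nrow(d),
         " observed cells (need at least 10)")
  }
  if (!all(is.finite(as.matrix(d[, c("elev", "lat", "lon")])))) {
    stop("non-finite covariates among training cells")
  }
  X <- as.matrix(d[, c("elev", "lat", "lon")])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y <- d$mod
  # a constant response leaves eps-SVR with no support vectors; short-circuit
  if (stats::sd(y) == 0) {
    return(structure(list(svm = NULL, constant = y[1], center = ctr,
                          scale = scl, train_z = Z, train_y = y,
                          cell_ids = d$cell_id,
                          hyper = list(cost = NA, gamma = NA, epsilon = NA),
                          cv_rmse = 0, r2 = 1,
                          predictor_names = c("elev", "lat", "lon")),
                     class = "interpolation_model"))
  }
  fold <- (seq_len(nrow(Z)) - 1L) %% folds + 1L
  grid <- expand.grid(cost = cost, gamma = gamma, epsilon = epsilon)
  cv_rmse <- apply(grid, 1, function(h) {
    err <- unlist(lapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (sum(tr) < 2 || sum(!tr) == 0) return(numeric(0))
      fit <- e1071::svm(Z[tr, , drop = FALSE], y[tr], type = "eps-regression",
                        kernel = "radial", cost = h[["cost"]],
                        gamma = h[["gamma"]], epsilon = h[["epsilon"]],
                        scale = FALSE)
      stats::predict(fit, Z[!tr, , drop = FALSE]) - y[!tr]
    }))
    sqrt(mean(err^2))
  })
  best <- grid[which.min(cv_rmse), ]
  fit <- e1071::svm(Z, y, type = "eps-regression", kernel = "radial",
                    cost = best$cost, gamma = best$gamma,
                    epsilon = best$epsilon, scale = FALSE)
  pred <- stats::predict(fit, Z)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(list(svm = fit, center = ctr, scale = scl, train_z = Z,
                 train_y = y, cell_ids = d$cell_id,
                 hyper = as.list(best), cv_rmse = min(cv_rmse), r2 = r2,
                 predictor_names = c("elev", "lat", "lon")),
            class = "interpolation_model")
}

#' @export
print.interpolation_model <- function(x, ...) {
  cat(sprintf(
    "SVR interpolator: %d training cells, cost=%g gamma=%g eps=%g, CV RMSE=%.2f d, R2=%.3f\n",
    length(x$cell_ids), x$hyper$cost, x$hyper$gamma, x$hyper$epsilon,
    x$cv_rmse, x$r2))
  invisible(x)
}

#' Predict MOD at arbitrary cells
#'
#' @param object An `interpolation_model`.
#' @param covariates data.frame `cell_id`, `elev`, `lat`, `lon`.
#' @param ... Unused.
#' @return Numeric predicted MOD, one per row of `covariates`.
#' @export
predict.interpolation_model <- function(object, covariates, ...) {
  if (is.null(object$svm)) {
    return(rep(object$constant, nrow(covariates)))
  }
  X <- as.matrix(covariates[, object$predictor_names])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as.numeric(stats::predict(object$svm, Z))
}

# pairwise minimum distance from rows of A to rows of B (standardized space)
.min_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Area of applicability of the interpolator
#'
#' Dissimilarity index (DI) per target cell = minimum Euclidean distance in
#' standardized predictor space to any training cell, normalized by the
#' mean pairwise distance among training cells. The threshold is the upper
#' whisker (75th percentile + 1.5 IQR) of the training cells' leave-one-out
#' DIs; cells at or below the threshold are inside the AOA and may be
#' interpolated.
#'
#' @param model An `interpolation_model`.
#' @param covariates data.frame with `cell_id` and the model predictors.
#' @param target_cells Cell ids to assess (default: all rows of
#'   `covariates`).
#' @return data.frame of class `aoa_mask`: `cell_id`,
#'   `dissimilarity_index`, `threshold`, `inside`. The training LOO DIs are
#'   attached as attribute `train_di`.
#' @export
area_of_applicability <- function(model, covariates,
                                  target_cells = covariates$cell_id) {
  Zt <- model$train_z
  n <- nrow(Zt)
  dmat <- as.matrix(stats::dist(Zt))
  dbar <- mean(dmat[upper.tri(dmat)])
  if (dbar == 0) dbar <- 1   # degenerate all-identical training cloud
  loo <- vapply(seq_len(n), function(i) min(dmat[i, -i]), numeric(1)) / dbar
  thr <- as.numeric(stats::quantile(loo, 0.75) + 1.5 * stats::IQR(loo))
  rows <- covariates[match(target_cells, covariates$cell_id), , drop = FALSE]
  if (anyNA(rows$cell_id)) stop("target cells missing from covariates")
  X <- as.matrix(rows[, model$predictor_names])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  di <- .min_dist(Z, Zt) / dbar
  out <- data.frame(cell_id = rows$cell_id, dissimilarity_index = di,
                    threshold = thr, inside = di <= thr)
  rownames(out) <- NULL
  attr(out, "train_di") <- loo
  class(out) <- c("aoa_mask", "data.frame")
  out
}

#' Fill under-sampled cells inside the area of applicability
#'
#' Adds interpolated MOD rows for cells that are inside the AOA and not
#' already observed. Observed values are never overwritten; cells outside
#' the AOA are excluded and reported.
#'
#' @param mod_grid Observed `mod_grid` rows for one species x year.
#' @param model The `interpolation_model` trained on those rows.
#' @param aoa An `aoa_mask` computed with the same model.
#' @param covariates data.frame `cell_id`, `elev`, `lat`, `lon`.
#' @return `mod_grid` with observed plus `provenance = "interpolated"` rows;
#'   attribute `excluded_outside_aoa` lists rejected cell ids.
#' @export
fill_grid <- function(mod_grid, model, aoa, covariates) {
  mg <- as.data.frame(mod_grid)
  candidates <- setdiff(aoa$cell_id[aoa$inside], mg$cell_id)
  outside <- setdiff(aoa$cell_id[!aoa$inside], mg$cell_id)
  if (length(candidates)) {
    cv <- covariates[match(candidates, covariates$cell_id), , drop = FALSE]
    pred <- predict(model, cv)
    add <- data.frame(
      species = mg$species[1], year = mg$year[1], cell_id = candidates,
      n = NA_integer_, mod = pred, mod_naive = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, provenance = "interpolated")
    mg <- rbind(mg, add)
  }
  rownames(mg) <- NULL
  attr(mg, "excluded_outside_aoa") <- outside
  class(mg) <- c("mod_grid", "data.frame")
  mg
}
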