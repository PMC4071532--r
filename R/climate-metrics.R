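#' Cellwise ensemble mean of congruent climate grids
#'
#' Averages several general-circulation-model grids for the same epoch and
#' variable (e.g. MIROC3 and CCSM) into a single consensus field. A cell is
#' missing in the output if it is missing in any input.
#'
#' @param grids list of congruent [climate_grid] objects.
#' @return a [climate_grid] with the cellwise arithmetic mean.
#' @export
ensemble_mean <- function(grids) {
  if (!length(grids)) mp_stop("empty grid list", "invalid_config")
  for (g in grids) check_congruent(grids[[1]], g)
  acc <- grids[[1]]$values
  if (length(grids) > 1) {
    for (g in grids[-1]) acc <- acc + g$values  # NA propagates by arithmetic
    acc <- acc / length(grids)
  }
  climate_grid(acc, grids[[1]]$cell_size_m,
               epoch = grids[[1]]$epoch, variable = grids[[1]]$variable)
}

#' Climate-change anomaly between two epochs
#'
#' Cellwise absolute difference `|a - b|`; magnitude of change, not direction.
#'
#' @param epoch_a,epoch_b congruent [climate_grid] objects for the two epochs.
#' @return a [climate_grid] of the anomaly, epoch labelled `"a-b"`.
#' @export
compute_anomaly <- function(epoch_a, epoch_b) {
  check_congruent(epoch_a, epoch_b)
  climate_grid(abs(epoch_a$values - epoch_b$values), epoch_a$cell_size_m,
               epoch = paste0(epoch_a$epoch, "-", epoch_b$epoch),
               variable = epoch_a$variable)
}

#' Spatial gradient magnitude of a gridded field
#'
#' Central differences over the 3x3 neighbourhood for interior cells and
#' one-sided differences at edges, returning `sqrt(gx^2 + gy^2)` in variable
#' units per metre. Cells adjacent to missing cells fall back to one-sided
#' differences where possible and are `NA` when no finite difference exists.
#'
#' @param grid a [climate_grid], at least 3x3.
#' @return a [climate_grid] of gradient magnitudes (units per m).
#' @export
spatial_gradient <- function(grid) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) mp_stop("grid must be at least 3x3", "size_error")
  h <- grid$cell_size_m
  diff1 <- function(lo, mid, hi) {
    # central when both sides present, else one-sided, else NA
    out <- (hi - lo) / (2 * h)
    left <- (mid - lo) / h
    right <- (hi - mid) / h
    out[is.na(out)] <- right[is.na(out)]
    out[is.na(out)] <- left[is.na(out)]
    out
  }
  pad <- function(m, side) {
    # replicate edge so the one-sided formula emerges from the central one
    switch(side,
      top = rbind(m[1, , drop = FALSE] * NA, m[-nr, , drop = FALSE]),
      bottom = rbind(m[-1, , drop = FALSE], m[nr, , drop = FALSE] * NA),
      left = cbind(m[, 1, drop = FALSE] * NA, m[, -nc, drop = FALSE]),
      right = cbind(m[, -1, drop = FALSE], m[, nc, drop = FALSE] * NA))
  }
  gy <- diff1(pad(v, "top"), v, pad(v, "bottom"))
  gx <- diff1(pad(v, "left"), v, pad(v, "right"))
  mag <- sqrt(gx^2 + gy^2)
  climate_grid(mag, h, epoch = grid$epoch,
               variable = paste0(grid$variable, "_gradient"))
}

#' Climate-change velocity surface
#'
#' Rate of displacement `v = (anomaly / years) / gradient` in metres per year:
#' the speed at which conditions move across the landscape, i.e. how fast a
#' species must shift its range to track climate. Gradients below `g_min` are
#' floored at `g_min` so flat cells get large finite velocities instead of
#' infinities.
#'
#' @param anomaly,gradient congruent [climate_grid]s (anomaly in variable
#'   units; gradient in units per m).
#' @param years epoch separation in years (> 0); 21000 for LGM-to-present,
#'   109000 for LIG-to-LGM.
#' @param g_min gradient floor in units per m.
#' @return a [climate_grid] of velocities (m per yr).
#' @export
velocity_surface <- function(anomaly, gradient, years, g_min = 1e-6) {
  check_congruent(anomaly, gradient)
  if (!is.numeric(years) || length(years) != 1 || years <= 0) {
    mp_stop("years must be a single positive number", "invalid_config")
  }
  g <- pmax(gradient$values, g_min)
  v <- (anomaly$values / years) / g
  climate_grid(v, anomaly$cell_size_m, epoch = anomaly$epoch,
               variable = paste0(anomaly$variable, "_velocity"))
}

#' Standardize nonnegative scores to [0, 1]
#'
#' `s_i = sqrt(v_i) / max_j sqrt(v_j)`: square-root then divide by the
#' maximum, so the largest score is exactly 1.
#'
#' @param values nonnegative numeric vector with a positive maximum.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
standardize_scores <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    mp_stop("scores require nonnegative input", "invalid_config")
  }
  mx <- max(values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    mp_stop("all-zero (or all-missing) input cannot be standardized",
            "degenerate_input")
  }
  sqrt(values) / sqrt(mx)
}

#' Aggregate a gridded field to regions
#'
#' Zonal statistic over the cells each region owns; missing cells are ignored.
#' A region with no valid cell is an error (never a silent `NA`).
#'
#' @param grid a [climate_grid].
#' @param membership integer matrix, same shape as the grid, giving the owning
#'   region id of each cell (`NA` = unassigned/ocean).
#' @param stat `"mean"` (arithmetic mean) or `"range"` (max - min).
#' @return named numeric vector indexed by region id.
#' @export
aggregate_to_regions <- function(grid, membership, stat = c("mean", "range")) {
  stat <- match.arg(stat)
  if (!identical(dim(grid$values), dim(membership))) {
    mp_stop("membership map shape differs from grid", "congruence_error")
  }
  keep <- !is.na(membership) & !is.na(grid$values)
  ids <- sort(unique(membership[!is.na(membership)]))
  vals <- split(grid$values[keep], membership[keep])
  missing_ids <- setdiff(ids, as.integer(names(vals)))
  if (length(missing_ids)) {
    mp_stop(paste0("regions with no valid cells: ",
                   paste(missing_ids, collapse = ", ")), "coverage_error")
  }
  out <- vapply(vals, function(v) {
    if (stat == "mean") mean(v) else max(v) - min(v)
  }, 0.0)
  out[order(as.integer(names(out)))]
}

#' Classify 1-D scores by k-means
#'
#' Seeded k-means on a one-dimensional score vector; class labels are
#' relabelled in increasing order of class centroid so label 1 is always the
#' lowest-score class. Used to re-express continuous climate scores as
#' categories for the categorical-climate sensitivity analysis.
#'
#' @param scores numeric vector.
#' @param k number of classes (>= 2, <= number of distinct values).
#' @param seed integer seed for the k-means initialization.
#' @return integer vector of class labels in `1..k`, with centroids in
#'   attribute `"centers"`.
#' @export
kmeans_classes <- function(scores, k, seed = 1) {
  n_distinct <- length(unique(scores))
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k > n_distinct) {
    mp_stop("k must be >= 2 and <= the number of distinct score values",
            "invalid_config")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483629))
  km <- stats::kmeans(matrix(scores, ncol = 1), centers = k, nstart = 25,
                      iter.max = 100)
  ord <- order(km$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(relabel[km$cluster], centers = sort(km$centers[, 1]))
}

## save/restore the RNG state so seeded helpers do not clobber callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
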