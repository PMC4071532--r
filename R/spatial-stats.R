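#' k-nearest-neighbour spatial weights
#'
#' Connects each observation to its `k` closest neighbours (planar km
#' distance by default, great-circle on a 6371 km sphere when
#' `great_circle = TRUE` and coordinates are lon/lat degrees), row-standardized
#' so each row of the weight matrix has `k` entries of `1/k`. The underlying
#' adjacency may be asymmetric, as usual for k-NN graphs.
#'
#' @param coords two-column matrix of coordinates (x/y km, or lon/lat deg).
#' @param k number of neighbours (0 < k < n).
#' @param great_circle logical; use spherical distances.
#' @return object of class `knn_weights`: list with `neighbours` (n x k
#'   integer matrix), `n`, `k`, `style = "W"`, `coords`.
#' @export
knn_weights <- function(coords, k = 4, great_circle = FALSE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1 || k >= n) mp_stop("k must satisfy 0 < k < n", "invalid_config")
  if (anyDuplicated(coords)) {
    mp_stop("duplicate coordinates: k-NN weights undefined", "degeneracy_error")
  }
  d <- if (great_circle) great_circle_dist(coords) else
    as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  if (k == 1) nb <- matrix(nb, ncol = 1)
  structure(list(neighbours = nb, n = n, k = k, style = "W", coords = coords),
            class = "knn_weights")
}

great_circle_dist <- function(lonlat, radius_km = 6371) {
  rad <- pi / 180
  lon <- lonlat[, 1] * rad; lat <- lonlat[, 2] * rad
  n <- length(lon)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cosang <- sin(lat[i]) * sin(lat) + cos(lat[i]) * cos(lat) * cos(lon - lon[i])
    d[i, ] <- radius_km * acos(pmin(pmax(cosang, -1), 1))
  }
  d
}

#' Row-standardized sparse weight matrix of a `knn_weights` object
#'
#' @param w a [knn_weights].
#' @return a sparse `dgCMatrix` with row sums 1 and zero diagonal.
#' @export
weights_matrix <- function(w) {
  stopifnot(inherits(w, "knn_weights"))
  Matrix::sparseMatrix(
    i = rep(seq_len(w$n), each = w$k),
    j = as.vector(t(w$neighbours)),
    x = 1 / w$k, dims = c(w$n, w$n)
  )
}

#' @export
print.knn_weights <- function(x, ...) {
  cat(sprintf("<knn_weights> n = %d, k = %d, style = %s\n", x$n, x$k, x$style))
  invisible(x)
}

#' Concentrated SAR error-model log-likelihood at a given lambda
#'
#' For `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)`:
#' applies the spatial filter `A = I - lambda W` to both sides, profiles out
#' `beta` (least squares on the filtered data) and `sigma^2 = RSS/n`, and
#' returns `-(n/2) (log(2 pi sigma^2) + 1) + log|A|`. Exposed so the profile
#' can be checked against a dense brute-force evaluation.
#'
#' @param lambda autocorrelation parameter.
#' @param X design matrix (full column rank).
#' @param y response vector.
#' @param W a [knn_weights] or a row-standardized sparse/dense weight matrix.
#' @return scalar log-likelihood, or `-Inf` when `I - lambda W` is not
#'   positive-determinant.
#' @export
sar_profile_loglik <- function(lambda, X, y, W) {
  Wm <- if (inherits(W, "knn_weights")) weights_matrix(W) else methods::as(W, "CsparseMatrix")
  n <- length(y)
  A <- Matrix::Diagonal(n) - lambda * Wm
  ld <- Matrix::determinant(A, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  ys <- as.numeric(A %*% y)
  Xs <- as.matrix(A %*% X)
  fit <- stats::lm.fit(Xs, ys)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  -(n / 2) * (log(2 * pi * sigma2) + 1) + as.numeric(ld$modulus)
}

#' Fit a simultaneous autoregressive error model by maximum likelihood
#'
#' SAR model of the error type: `y = X beta + u`, `u = lambda W u + eps`.
#' `lambda` is found by maximizing the concentrated log-likelihood over a
#' grid on (-0.999, 0.999) followed by golden-section refinement of the
#' bracketed optimum; the log-determinant is evaluated by sparse LU at each
#' candidate. Standard errors come from the inverse numerical Hessian of the
#' full log-likelihood at the optimum, giving Z statistics for each
#' coefficient. `AIC = -2 logLik + 2 (p + 2)`, counting `lambda` and
#' `sigma^2`.
#'
#' @param X design matrix with named columns (include the intercept column).
#' @param y response vector (here: arcsine-square-root proportions).
#' @param W a [knn_weights] (row-standardized).
#' @param lambda_fixed optional: skip estimation and fit at this lambda.
#' @param grid_n number of grid points in the bracketing stage.
#' @return object of class `sar_fit`: coefficients, `se`, `z`, `p`,
#'   `lambda`, `lambda_se`, `sigma2`, `loglik`, `aic`, `fitted_trend`
#'   (`X beta`), `residuals` (`y - X beta`), `innovations`
#'   (`(I - lambda W)(y - X beta)`), `pseudo_r2`, `n`.
#' @export
sar_error_fit <- function(X, y, W, lambda_fixed = NULL, grid_n = 21) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) {
    mp_stop("design matrix is rank deficient", "design_error")
  }
  n <- length(y)
  Wm <- weights_matrix(W)

  if (is.null(lambda_fixed)) {
    grid <- seq(-0.999, 0.999, length.out = grid_n)
    ll <- vapply(grid, function(l) sar_profile_loglik(l, X, y, Wm), 0.0)
    if (all(!is.finite(ll))) {
      mp_stop("concentrated likelihood non-finite on entire grid",
              "estimation_error")
    }
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
    opt <- stats::optimize(function(l) sar_profile_loglik(l, X, y, Wm),
                           lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-7)
    lambda <- opt$maximum
  } else {
    lambda <- lambda_fixed
  }

  A <- Matrix::Diagonal(n) - lambda * Wm
  ys <- as.numeric(A %*% y)
  Xs <- as.matrix(A %*% X)
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  sigma2 <- sum(fit$residuals^2) / n
  loglik <- sar_profile_loglik(lambda, X, y, Wm)
  p <- ncol(X)
  aic <- -2 * loglik + 2 * (p + 2)

  full_ll <- function(theta) {
    b <- theta[seq_len(p)]; l <- theta[p + 1]; ls2 <- theta[p + 2]
    if (abs(l) >= 0.9999) return(-Inf)
    s2 <- exp(ls2)
    Al <- Matrix::Diagonal(n) - l * Wm
    ld <- Matrix::determinant(Al, logarithm = TRUE)
    if (ld$sign <= 0) return(-Inf)
    e <- as.numeric(Al %*% (y - drop(X %*% b)))
    -(n / 2) * log(2 * pi * s2) + as.numeric(ld$modulus) - sum(e^2) / (2 * s2)
  }
  theta_hat <- c(beta, lambda, log(sigma2))
  H <- num_hessian(full_ll, theta_hat)
  se <- rep(NA_real_, p); lambda_se <- NA_real_
  cov <- try(solve(-H), silent = TRUE)
  if (!inherits(cov, "try-error")) {
    dg <- diag(cov)
    if (all(dg[seq_len(p + 1)] > 0)) {
      se <- sqrt(dg[seq_len(p)])
      lambda_se <- sqrt(dg[p + 1])
    }
  }
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  trend <- drop(X %*% beta)
  resid <- y - trend
  innov <- as.numeric(A %*% resid)
  structure(
    list(coefficients = beta, se = se, z = z, p = pval,
         lambda = lambda, lambda_se = lambda_se, sigma2 = sigma2,
         loglik = loglik, aic = aic, fitted_trend = trend,
         residuals = resid, innovations = innov,
         pseudo_r2 = pseudo_r2(trend, y), n = n, n_par = p + 2, X = X, y = y),
    class = "sar_fit"
  )
}

## central-difference Hessian; steps scaled to parameter magnitude
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-4
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("SAR error model (maximum likelihood)\n")
  tab <- data.frame(estimate = x$coefficients, s.d. = x$se, Z = x$z, p = x$p)
  print(round(tab, 4))
  cat(sprintf("lambda = %.4f (se %.4f), sigma2 = %.5f\n",
              x$lambda, x$lambda_se, x$sigma2))
  cat(sprintf("logLik = %.3f, AIC = %.2f, pseudo-R2 = %.3f, n = %d\n",
              x$loglik, x$aic, x$pseudo_r2, x$n))
  invisible(x)
}

#' Trend prediction from a SAR error fit
#'
#' The trend component `X beta` only (no spatial smoothing term); optionally
#' back-transformed to the proportion scale via `sin^2` of the `[0, pi/2]`-
#' clamped trend.
#'
#' @param fit a [sar_error_fit] result.
#' @param X_new design matrix with the fitted columns.
#' @param back_transform logical; return proportions instead of the arcsine
#'   scale.
#' @return numeric vector of predictions.
#' @export
predict_sar_trend <- function(fit, X_new, back_transform = FALSE) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(fit$coefficients)) {
    mp_stop("X_new columns do not match fitted coefficients", "design_error")
  }
  tr <- unname(drop(X_new %*% fit$coefficients))
  if (back_transform) sin(pmin(pmax(tr, 0), pi / 2))^2 else tr
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * sum_ij w_ij (z_i - zbar)(z_j - zbar) / sum_i (z_i - zbar)^2`
#' with `S0` the sum of all weights. Null expectation is `-1/(n-1)`.
#'
#' @param z numeric vector with nonzero variance.
#' @param w a [knn_weights] object or an n x n (sparse) weight matrix.
#' @return scalar Moran's I.
#' @export
morans_i <- function(z, w) {
  Wm <- if (inherits(w, "knn_weights")) weights_matrix(w) else
    methods::as(w, "CsparseMatrix")
  n <- length(z)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom == 0) mp_stop("zero-variance input", "degenerate_input")
  s0 <- sum(Wm)
  if (s0 == 0) mp_stop("no weighted pairs", "degenerate_input")
  (n / s0) * as.numeric(zc %*% (Wm %*% zc)) / denom
}

#' Moran's I correlogram with permutation tests
#'
#' Bins all point pairs into contiguous distance classes of fixed width
#' starting at 0, computes Moran's I per class with binary pair-membership
#' weights, and attaches a two-sided permutation p-value per class (the same
#' permutations are reused across classes, seeded). Empty classes are
#' reported with `NA` statistics, never as zero.
#'
#' @param residuals numeric vector (e.g. model residuals).
#' @param coords two-column coordinate matrix (km).
#' @param class_width_km distance-class width (default 500 km).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @param great_circle logical; spherical distances for lon/lat input.
#' @return data frame of class `correlogram`: class_lo_km, class_hi_km,
#'   n_pairs, moran_i, p_perm.
#' @export
correlogram <- function(residuals, coords, class_width_km = 500,
                        n_perm = 999, seed = 1, great_circle = FALSE) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (anyDuplicated(coords)) {
    mp_stop("duplicate coordinates", "degeneracy_error")
  }
  d <- if (great_circle) great_circle_dist(coords) else
    as.matrix(stats::dist(coords))
  maxd <- max(d)
  n_classes <- ceiling(maxd / class_width_km)
  if (n_classes < 1) n_classes <- 1L
  if (n_classes == 1 && maxd > 0) {
    mp_warn("all pairs fall in a single distance class; widen or shrink class width",
            "class_width_warning")
  }
  ut <- upper.tri(d)
  cls <- pmin(ceiling(d / class_width_km), n_classes)
  cls[d == 0] <- 1L

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483629))
  perms <- replicate(n_perm, sample.int(n))

  out <- data.frame(class_lo_km = (seq_len(n_classes) - 1) * class_width_km,
                    class_hi_km = seq_len(n_classes) * class_width_km,
                    n_pairs = NA_integer_, moran_i = NA_real_,
                    p_perm = NA_real_)
  zc <- residuals - mean(residuals)
  denom <- sum(zc^2)
  if (denom == 0) mp_stop("zero-variance residuals", "degenerate_input")
  Zp <- matrix(residuals[perms], n, n_perm)
  Zp <- sweep(Zp, 2, colMeans(Zp))
  for (cl in seq_len(n_classes)) {
    sel <- which(ut & cls == cl, arr.ind = TRUE)
    out$n_pairs[cl] <- nrow(sel)
    if (!nrow(sel)) next
    Wc <- Matrix::sparseMatrix(i = c(sel[, 1], sel[, 2]),
                               j = c(sel[, 2], sel[, 1]),
                               x = 1, dims = c(n, n))
    s0 <- 2 * nrow(sel)
    i_obs <- (n / s0) * as.numeric(zc %*% (Wc %*% zc)) / denom
    cross <- Matrix::colSums(Zp * (Wc %*% Zp))
    i_perm <- (n / s0) * as.numeric(cross) / colSums(Zp^2)
    ctr <- mean(i_perm)
    p <- (1 + sum(abs(i_perm - ctr) >= abs(i_obs - ctr))) / (n_perm + 1)
    out$moran_i[cl] <- i_obs
    out$p_perm[cl] <- p
  }
  class(out) <- c("correlogram", class(out))
  out
}

#' Pseudo R-squared of a trend prediction
#'
#' Squared Pearson correlation between the observed response and the fitted
#' trend; the goodness-of-fit surrogate reported for SAR models. A constant
#' trend has undefined correlation and is reported as 0 with a warning.
#'
#' @param trend fitted trend values (or a `sar_fit`, whose trend is used).
#' @param y observed response.
#' @return value in `[0, 1]`.
#' @export
pseudo_r2 <- function(trend, y) {
  if (inherits(trend, "sar_fit")) trend <- trend$fitted_trend
  if (stats::sd(trend) == 0) {
    mp_warn("constant trend: pseudo-R2 undefined, reporting 0",
            "degenerate_input")
    return(0)
  }
  stats::cor(y, trend)^2
}
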