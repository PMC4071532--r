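# Independent oracles. Each reimplements the checked quantity by brute force
# or closed form, sharing no code with the package's computational path.

# Dense-matrix SAR error-model profile log-likelihood: explicit determinant,
# explicit GLS, no sparse machinery.
dense_sar_loglik <- function(lambda, X, y, Wdense) {
  n <- length(y)
  A <- diag(n) - lambda * Wdense
  dt <- det(A)
  if (dt <= 0) return(-Inf)
  ys <- A %*% y
  Xs <- A %*% X
  beta <- solve(t(Xs) %*% Xs, t(Xs) %*% ys)
  rss <- sum((ys - Xs %*% beta)^2)
  s2 <- rss / n
  -(n / 2) * (log(2 * pi * s2) + 1) + log(dt)
}

# Brute-force central/one-sided difference gradient magnitude, cell by cell.
brute_gradient <- function(v, h) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  d1 <- function(lo, mid, hi) {
    if (!is.na(lo) && !is.na(hi)) (hi - lo) / (2 * h)
    else if (!is.na(hi)) (hi - mid) / h
    else if (!is.na(lo)) (mid - lo) / h
    else NA_real_
  }
  at <- function(r, c) if (r >= 1 && r <= nr && c >= 1 && c <= nc) v[r, c] else NA_real_
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gy <- d1(at(r - 1, c), v[r, c], at(r + 1, c))
    gx <- d1(at(r, c - 1), v[r, c], at(r, c + 1))
    out[r, c] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Full distance-matrix sort k-NN.
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  t(sapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  }))
}

# Exhaustive simple-path enumeration between two node sets on a small graph;
# path cost = sum of entry costs of every node after the first.
brute_best_path <- function(adj, cost, from_set, to_set, max_len = 10) {
  best <- NULL
  recurse <- function(path) {
    v <- path[length(path)]
    if (v %in% to_set && length(path) > 1) {
      cst <- sum(cost[path[-1]])
      if (is.null(best) || cst < best$cost) best <<- list(path = path, cost = cst)
      return()
    }
    if (length(path) >= max_len) return()
    for (nb in adj[[v]]) {
      if (!(nb %in% path)) recurse(c(path, nb))
    }
  }
  for (s in from_set) recurse(s)
  best
}

# Hand one-way ANOVA F for a two-group design.
hand_anova_f <- function(y, g) {
  m <- tapply(y, g, mean)
  n <- table(g)
  gm <- mean(y)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((y - m[as.character(g)])^2)
  df1 <- length(m) - 1
  df2 <- length(y) - length(m)
  (ssb / df1) / (ssw / df2)
}

# Exhaustive threshold search for 1-D two-class k-means (minimal within-SS).
brute_kmeans2_1d <- function(x) {
  xs <- sort(unique(x))
  best <- NULL
  for (t in xs[-length(xs)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || ss < best$ss) best <- list(thresh = t, ss = ss)
  }
  best
}

# Small fixture worlds shared across files.
tiny_world <- function(seed = 1, n_regions = 12, grid = c(4, 6),
                       n_continents = 2) {
  generate_regions(world_config(n_regions = n_regions, grid_shape = grid,
                                cell_size_km = 100,
                                n_continents = n_continents, seed = seed))
}

default_world <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_regions(world_config(seed = seed))
    }
    cache[[key]]
  }
})

# Standardized temperature-anomaly scores of the default synthetic climate.
default_ta <- function(world, seed = 1) {
  pair <- generate_epoch_pair(world$cfg, seed = seed)
  anom <- compute_anomaly(pair[[1]], pair[[2]])
  standardize_scores(aggregate_to_regions(anom, world$membership, "mean"))
}

# Design matrix of the reference model (intercept, HS, AC, TA, HS:TA, AC:TA).
reference_design <- function(world, ta) {
  lump <- lump_archaic(world$regions$hominin)
  hs <- as.numeric(lump == "Hsapiens-only")
  ac <- as.numeric(lump == "Archaic-combined")
  cbind(`(Intercept)` = 1, hs = hs, ac = ac, ta = ta,
        hs_ta = hs * ta, ac_ta = ac * ta)
}
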