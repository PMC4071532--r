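#' Configuration of the synthetic study system
#'
#' The synthetic world is a planar lattice of climate cells partitioned into
#' contiguous analysis regions (stand-ins for TDWG level 3 countries), grouped
#' into contiguous continent blocks, each block carrying one hominin
#' palaeobiogeography class. Geometry is planar and in kilometres: projection
#' questions are deliberately out of the synthetic mode.
#'
#' Default dimensions mirror the study system: 229 regions across 6 continent
#' blocks on a 40 x 60 lattice of 100 km cells.
#'
#' @param n_regions number of analysis regions (>= 8).
#' @param grid_shape integer `c(rows, cols)` of the climate lattice.
#' @param cell_size_km cell edge length in km.
#' @param n_continents number of contiguous continent blocks.
#' @param hominin_map character vector, one hominin class per continent, from
#'   `hominin_classes()`. Default emulates the global configuration: one
#'   origin continent, three archaic-exposure continents, two continents first
#'   reached by modern humans.
#' @param seed integer seed.
#' @return object of class `world_config`.
#' @export
world_config <- function(n_regions = 229, grid_shape = c(40, 60),
                         cell_size_km = 100, n_continents = 6,
                         hominin_map = NULL, seed = 1) {
  if (n_regions < 8) mp_stop("n_regions must be >= 8", "invalid_config")
  if (n_regions > prod(grid_shape)) {
    mp_stop("n_regions exceeds number of lattice cells", "invalid_config")
  }
  if (n_continents < 1 || n_continents > n_regions) {
    mp_stop("n_continents must be in [1, n_regions]", "invalid_config")
  }
  if (is.null(hominin_map)) {
    base <- c("Homo-origin", "Archaic-early", "Archaic-late",
              "Archaic-peripheral", "Hsapiens-only", "Hsapiens-only")
    hominin_map <- rep_len(base, n_continents)
  }
  if (length(hominin_map) != n_continents) {
    mp_stop("hominin_map must have one class per continent", "invalid_config")
  }
  bad <- setdiff(hominin_map, hominin_classes())
  if (length(bad)) {
    mp_stop(paste("unknown hominin class:", paste(bad, collapse = ", ")),
            "invalid_config")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         grid_shape = as.integer(grid_shape),
         cell_size_km = as.numeric(cell_size_km),
         n_continents = as.integer(n_continents),
         hominin_map = hominin_map, seed = as.integer(seed)),
    class = "world_config"
  )
}

#' The five hominin palaeobiogeography classes
#'
#' Ordered by length of hominin-megafauna co-occurrence: the hominin origin
#' region, three classes of archaic-hominin exposure (early, late,
#' peripheral), and regions where modern humans were the first hominin.
#'
#' @return character vector of the five class labels, in ordinal order.
#' @export
hominin_classes <- function() {
  c("Homo-origin", "Archaic-early", "Archaic-late", "Archaic-peripheral",
    "Hsapiens-only")
}

#' Lump the five hominin classes to the three-level coding
#'
#' Collapses the three archaic classes to `"Archaic-combined"`, keeping
#' `"Homo-origin"` and `"Hsapiens-only"`, the coding the ordinal analysis
#' selects.
#'
#' @param x character vector of five-level class labels.
#' @return factor with levels Homo-origin, Archaic-combined, Hsapiens-only.
#' @export
lump_archaic <- function(x) {
  out <- ifelse(grepl("^Archaic", x), "Archaic-combined", x)
  factor(out, levels = c("Homo-origin", "Archaic-combined", "Hsapiens-only"))
}

#' Parameters of the extinction data-generating process
#'
#' Linear predictor on the arcsine scale with the reference coefficient
#' schema (intercept; modern-human-only region HS; archaic-combined region
#' AC; standardized temperature anomaly TA; HS x TA; AC x TA), plus
#' simultaneous-autoregressive error structure.
#'
#' Default `beta` is the reference fit of the study system; `lambda = 0.6`
#' and `sigma = 0.15` give simulated proportion spreads resembling the
#' observed interquartile ranges (generator defaults, not estimates).
#'
#' @param beta length-6 coefficient vector (intercept, HS, AC, TA, HS:TA,
#'   AC:TA) on the arcsine scale.
#' @param lambda SAR error autocorrelation, strictly inside (-1, 1).
#' @param sigma error standard deviation (>= 0).
#' @param richness_range integer `c(min, max)` total large-mammal species per
#'   region (min >= 1).
#' @return object of class `dgp_params`.
#' @export
dgp_params <- function(beta = c(intercept = -0.353, hs = 1.107, ac = 0.735,
                                ta = 1.504, hs_ta = -1.516, ac_ta = -1.225),
                       lambda = 0.6, sigma = 0.15,
                       richness_range = c(10, 60)) {
  if (length(beta) != 6) mp_stop("beta must have 6 coefficients", "invalid_config")
  if (abs(lambda) >= 1) mp_stop("lambda must be inside (-1, 1)", "invalid_config")
  if (sigma < 0) mp_stop("sigma must be >= 0", "invalid_config")
  if (richness_range[1] < 1 || richness_range[2] < richness_range[1]) {
    mp_stop("richness_range must be increasing with min >= 1", "invalid_config")
  }
  structure(list(beta = beta, lambda = lambda, sigma = sigma,
                 richness_range = as.integer(richness_range)),
            class = "dgp_params")
}

#' Generate the region tessellation of a synthetic world
#'
#' Splits the lattice into contiguous continent blocks (vertical bands of
#' columns), allocates regions to continents proportionally to block area,
#' and grows each region from a random seed cell by stochastic breadth-first
#' accretion, so regions are contiguous and partition the lattice exactly.
#'
#' @param cfg a [world_config].
#' @return object of class `synthetic_world`: a list with `regions` (data
#'   frame: region_id, centroid_x_km, centroid_y_km, continent, hominin,
#'   n_cells), `membership` (integer matrix of owning region per lattice
#'   cell), `adjacency` (symmetric list of rook-neighbour region ids), and
#'   `cfg`.
#' @export
generate_regions <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]

  # continent blocks: contiguous vertical bands of whole columns
  band <- sort(rep_len(seq_len(cfg$n_continents), nc))
  cont_of_cell <- matrix(band[col(matrix(0, nr, nc))], nr, nc)

  # allocate region counts per continent by largest remainder, min 1
  cells_per_cont <- tabulate(band, cfg$n_continents) * nr
  quota <- cfg$n_regions * cells_per_cont / sum(cells_per_cont)
  n_per <- pmax(1L, floor(quota))
  rem <- cfg$n_regions - sum(n_per)
  if (rem > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    extra <- rep_len(ord, rem)
    for (i in extra) n_per[i] <- n_per[i] + 1L
  } else if (rem < 0) {
    ord <- order(n_per, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      if (n_per[ord[i]] > 1L) { n_per[ord[i]] <- n_per[ord[i]] - 1L; rem <- rem + 1 }
      i <- i %% cfg$n_continents + 1
    }
  }
  if (any(n_per > cells_per_cont)) {
    mp_stop("a continent block has more regions than cells", "invalid_config")
  }

  membership <- matrix(NA_integer_, nr, nc)
  next_id <- 1L
  idx <- function(r, c) (c - 1L) * nr + r
  for (ct in seq_len(cfg$n_continents)) {
    cells <- which(cont_of_cell == ct)         # linear indices
    seeds <- sample(cells, n_per[ct])
    membership[seeds] <- seq.int(next_id, next_id + n_per[ct] - 1L)
    next_id <- next_id + n_per[ct]
    frontier <- cells[is.na(membership[cells])]
    while (length(frontier)) {
      frontier <- frontier[sample.int(length(frontier))]
      assigned_any <- FALSE
      newly <- integer(0)
      for (cell in frontier) {
        r <- (cell - 1L) %% nr + 1L; c <- (cell - 1L) %/% nr + 1L
        nb <- c(if (r > 1) idx(r - 1L, c), if (r < nr) idx(r + 1L, c),
                if (c > 1) idx(r, c - 1L), if (c < nc) idx(r, c + 1L))
        nb <- nb[nb %in% cells]
        owners <- membership[nb]
        owners <- owners[!is.na(owners)]
        if (length(owners)) {
          membership[cell] <- owners[sample.int(length(owners), 1)]
          assigned_any <- TRUE
        } else newly <- c(newly, cell)
      }
      frontier <- newly
      if (!assigned_any && length(frontier)) {
        mp_stop("region growth stalled (disconnected continent block)",
                "invalid_config")
      }
    }
  }

  # centroids in km (cell centres)
  xs <- (col(membership) - 0.5) * cfg$cell_size_km
  ys <- (row(membership) - 0.5) * cfg$cell_size_km
  cx <- tapply(xs, membership, mean)
  cy <- tapply(ys, membership, mean)
  ncell <- tabulate(membership, cfg$n_regions)
  cont_of_region <- tapply(cont_of_cell, membership, function(v) v[1])

  regions <- data.frame(
    region_id = seq_len(cfg$n_regions),
    centroid_x_km = as.numeric(cx[as.character(seq_len(cfg$n_regions))]),
    centroid_y_km = as.numeric(cy[as.character(seq_len(cfg$n_regions))]),
    continent = as.integer(cont_of_region[as.character(seq_len(cfg$n_regions))]),
    n_cells = ncell
  )
  regions$hominin <- cfg$hominin_map[regions$continent]

  # distinct centroids are a postcondition (k-NN weights need them); break
  # exact collisions with a deterministic sub-metre nudge
  key <- paste(regions$centroid_x_km, regions$centroid_y_km)
  dup <- duplicated(key)
  if (any(dup)) {
    regions$centroid_x_km[dup] <- regions$centroid_x_km[dup] +
      regions$region_id[dup] * 1e-7
  }

  adjacency <- region_adjacency(membership)
  structure(list(regions = regions, membership = membership,
                 adjacency = adjacency, cfg = cfg),
            class = "synthetic_world")
}

## symmetric rook adjacency between regions from a membership matrix
region_adjacency <- function(membership) {
  nr <- nrow(membership); nc <- ncol(membership)
  a <- membership[-nr, ]; b <- membership[-1, ]
  c1 <- membership[, -nc]; c2 <- membership[, -1]
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(c2)))
  pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  n <- max(membership, na.rm = TRUE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- sort(pairs[pairs[, 1] == i, 2])
  adj
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d regions, %d continents, %d x %d lattice\n",
              nrow(x$regions), x$cfg$n_continents,
              x$cfg$grid_shape[1], x$cfg$grid_shape[2]))
  invisible(x)
}

#' Generate a spatially autocorrelated climate field
#'
#' Gaussian-kernel-smoothed white noise (unit variance after smoothing) on
#' top of a deterministic north-south linear trend, emulating a macroclimate
#' surface. With `smoothness_km = Inf` the field degenerates to the trend
#' alone (the infinite-correlation-length limit).
#'
#' @param cfg a [world_config].
#' @param epoch epoch label.
#' @param smoothness_km spatial correlation length in km (> 0, may be `Inf`).
#' @param seed integer seed.
#' @param trend_range `c(low, high)`: trend values at the first and last row
#'   (degrees C for temperature-like fields).
#' @param noise_sd marginal SD of the autocorrelated noise component.
#' @param variable variable label.
#' @param innovations optional pre-drawn standard-normal matrix (rows x cols)
#'   used as the white-noise input; used to build correlated epoch pairs.
#' @return a [climate_grid]; the deterministic trend component is attached as
#'   field `trend`.
#' @export
generate_climate_field <- function(cfg, epoch = "present", smoothness_km = 300,
                                   seed = 1, trend_range = c(25, -5),
                                   noise_sd = 3, variable = "temperature",
                                   innovations = NULL) {
  stopifnot(inherits(cfg, "world_config"))
  if (!is.numeric(smoothness_km) || smoothness_km <= 0) {
    mp_stop("smoothness_km must be positive", "invalid_config")
  }
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  trend <- matrix(seq(trend_range[1], trend_range[2], length.out = nr),
                  nr, nc)
  if (is.infinite(smoothness_km)) {
    g <- climate_grid(trend, cfg$cell_size_km * 1000, epoch, variable)
    g$trend <- trend
    return(g)
  }
  if (is.null(innovations)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(derive_seed(seed, 11)))
    innovations <- matrix(stats::rnorm(nr * nc), nr, nc)
  }
  z <- gaussian_smooth(innovations, sigma_cells = smoothness_km / cfg$cell_size_km)
  z <- z / stats::sd(z)
  g <- climate_grid(trend + noise_sd * z, cfg$cell_size_km * 1000, epoch,
                    variable)
  g$trend <- trend
  g
}

## separable Gaussian blur with edge renormalization
gaussian_smooth <- function(m, sigma_cells) {
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  smooth_1d <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(x[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Generate a correlated pair of epoch fields
#'
#' Two climate fields whose stochastic components are correlated at target
#' `r`, emulating the observed cross-epoch consistency of anomaly patterns.
#' The second epoch is additionally shifted by `delta` (e.g. a glacial
#' cooling offset).
#'
#' @inheritParams generate_climate_field
#' @param epochs labels for the two epochs.
#' @param r target correlation of the stochastic components, in `[-1, 1]`.
#' @param delta additive offset of the second epoch (variable units). A
#'   length-2 value `c(low_lat, high_lat)` grades the offset linearly across
#'   rows, emulating polar amplification: glacial cooling of roughly 1-3
#'   degrees in the tropics against 10-20 degrees at high latitudes, so the
#'   anomaly (and its standardized score) genuinely spans its range.
#' @return list of two [climate_grid]s named by epoch.
#' @export
generate_epoch_pair <- function(cfg, epochs = c("present", "lgm"),
                                smoothness_km = 300, r = 0.9,
                                delta = c(-2, -14),
                                seed = 1, trend_range = c(25, -5),
                                noise_sd = 3, variable = "temperature") {
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(derive_seed(seed, 23)))
  e1 <- matrix(stats::rnorm(nr * nc), nr, nc)
  e2 <- r * e1 + sqrt(1 - r^2) * matrix(stats::rnorm(nr * nc), nr, nc)
  g1 <- generate_climate_field(cfg, epochs[1], smoothness_km, seed,
                               trend_range, noise_sd, variable, innovations = e1)
  g2 <- generate_climate_field(cfg, epochs[2], smoothness_km, seed,
                               trend_range, noise_sd, variable, innovations = e2)
  offset <- if (length(delta) == 2) {
    matrix(seq(delta[1], delta[2], length.out = nr), nr, nc)
  } else matrix(delta, nr, nc)
  g2$values <- g2$values + offset
  stats::setNames(list(g1, g2), epochs)
}

#' Simulate per-region extinction outcomes from the reference linear predictor
#'
#' The data-generating process of the synthetic world: on the arcsine scale,
#' `eta = X beta + u` with simultaneous-autoregressive errors
#' `u = lambda W u + eps` solved exactly as `u = (I - lambda W)^-1 eps`,
#' where `W` is the row-standardized 4-nearest-neighbour weight matrix of the
#' region centroids (the same weights the analysis uses). The proportion is
#' the back-transform `p = sin^2(eta)` with `eta` clamped to `[0, pi/2]`
#' (the transform's invertible range), and the extinct count is
#' `round_half_up(p * total_species)`.
#'
#' @param world a [generate_regions] result (or its `regions` data frame plus
#'   a weights object via `W`).
#' @param ta_std per-region standardized temperature anomaly in `[0, 1]`.
#' @param params a [dgp_params].
#' @param seed integer seed.
#' @param W optional spatial weights (a [knn_weights] object); defaults to
#'   4-NN weights on the region centroids.
#' @return data frame: region_id, hominin, total_species, extinct_count,
#'   true_proportion, eta, trend (`X beta`), ta_std.
#' @export
generate_extinctions <- function(world, ta_std, params = dgp_params(),
                                 seed = 1, W = NULL) {
  regions <- if (inherits(world, "synthetic_world")) world$regions else world
  stopifnot(inherits(params, "dgp_params"))
  n <- nrow(regions)
  if (length(ta_std) != n || any(ta_std < 0 | ta_std > 1)) {
    mp_stop("ta_std must be per-region values in [0, 1]", "invalid_config")
  }
  if (is.null(W)) {
    W <- knn_weights(cbind(regions$centroid_x_km, regions$centroid_y_km), k = 4)
  }
  lump <- lump_archaic(regions$hominin)
  hs <- as.numeric(lump == "Hsapiens-only")
  ac <- as.numeric(lump == "Archaic-combined")
  X <- cbind(1, hs, ac, ta_std, hs * ta_std, ac * ta_std)
  xb <- drop(X %*% params$beta)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(derive_seed(seed, 37)))
  eps <- stats::rnorm(n, sd = params$sigma)
  u <- if (params$lambda == 0 || params$sigma == 0) {
    eps
  } else {
    A <- Matrix::Diagonal(n) - params$lambda * weights_matrix(W)
    as.numeric(Matrix::solve(A, eps))
  }
  eta <- xb + u
  p <- sin(pmin(pmax(eta, 0), pi / 2))^2
  total <- sample(seq.int(params$richness_range[1], params$richness_range[2]),
                  n, replace = TRUE)
  extinct <- as.integer(round_half_up(p * total))
  data.frame(region_id = regions$region_id, hominin = regions$hominin,
             total_species = total, extinct_count = extinct,
             true_proportion = p, eta = eta, trend = xb, ta_std = ta_std)
}

#' Generate a synthetic extinct-species inventory and presence matrix
#'
#' Emulates the schema of a curated species table (name, body mass, dating,
#' acceptance status, extinction scope) plus a binary species-by-region
#' presence matrix with contiguous ranges. Masses are log-normal so both mass
#' thresholds bite; a small fraction of records is dated outside the study
#' window or lacks a direct date so every acceptance filter is exercised.
#'
#' @param world a [generate_regions] result.
#' @param n_species number of species (default 177, the reference inventory
#'   size).
#' @param mass_meanlog,mass_sdlog log-normal body-mass parameters (kg).
#' @param window `c(old, young)` study window in years BP.
#' @param uncertain_fraction fraction of records with uncertain status.
#' @param seed integer seed.
#' @return list with `species` (data frame: species_id, name, mass_kg,
#'   status, direct_date, earliest_bp, latest_bp, scope) and `presence`
#'   (binary species x region matrix) and `provenance` (character matrix,
#'   `"direct"` where present).
#' @export
generate_species_table <- function(world, n_species = 177,
                                   mass_meanlog = log(100), mass_sdlog = 1.5,
                                   window = c(132000, 1000),
                                   uncertain_fraction = 27 / 204, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"), n_species >= 1)
  regions <- world$regions
  adj <- world$adjacency
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(derive_seed(seed, 53)))
  n <- as.integer(n_species)
  mass <- stats::rlnorm(n, mass_meanlog, mass_sdlog)
  status <- ifelse(stats::runif(n) < uncertain_fraction, "uncertain", "accepted")
  direct <- stats::runif(n) < 0.92
  # most intervals inside the window; ~5% entirely too recent or too old
  mid <- stats::runif(n, window[2], window[1])
  halfspan <- stats::runif(n, 500, 20000)
  earliest <- mid + halfspan
  latest <- pmax(mid - halfspan, 100)
  too_recent <- stats::runif(n) < 0.03
  earliest[too_recent] <- stats::runif(sum(too_recent), 300, window[2] - 1)
  latest[too_recent] <- pmax(earliest[too_recent] - 150, 50)
  too_old <- stats::runif(n) < 0.02
  latest[too_old] <- stats::runif(sum(too_old), window[1] + 1, window[1] + 40000)
  earliest[too_old] <- latest[too_old] + 10000
  scope <- ifelse(stats::runif(n) < 0.15, "continental", "global")

  nR <- nrow(regions)
  presence <- matrix(0L, n, nR,
                     dimnames = list(sprintf("sp%03d", seq_len(n)),
                                     regions$region_id))
  for (i in seq_len(n)) {
    size <- min(nR, 1L + stats::rgeom(1, prob = 1 / 8))
    occ <- sample.int(nR, 1)
    while (length(occ) < size) {
      cand <- setdiff(unique(unlist(adj[occ])), occ)
      if (!length(cand)) break
      occ <- c(occ, cand[sample.int(length(cand), 1)])
    }
    presence[i, occ] <- 1L
  }
  provenance <- ifelse(presence == 1L, "direct", "")
  species <- data.frame(
    species_id = rownames(presence),
    name = sprintf("Simulatus species%03d", seq_len(n)),
    mass_kg = mass, status = status, direct_date = direct,
    earliest_bp = round(earliest), latest_bp = round(latest), scope = scope
  )
  list(species = species, presence = presence, provenance = provenance)
}
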