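#' Apply the species acceptance filters
#'
#' A species record is retained iff: status is `"accepted"` (uncertain
#' records enter only when `include_uncertain = TRUE`, the sensitivity
#' configuration), body mass is at or above the threshold (inclusive, per
#' "more than or equal to"), a directly dated site exists, and the dated
#' interval intersects the study window. The window runs from 132 000 to
#' 1000 years BP by default: species lost in the last 1000 years are
#' excluded.
#'
#' @param records species data frame with columns `mass_kg`, `status`,
#'   `direct_date`, `earliest_bp`, `latest_bp`.
#' @param min_mass_kg mass threshold in kg (10 for the primary analysis, 44
#'   for the sensitivity run).
#' @param window `c(old, young)` years BP.
#' @param include_uncertain logical.
#' @return the retained subset (warning, not error, if empty).
#' @export
filter_species <- function(records, min_mass_kg = 10,
                           window = c(132000, 1000),
                           include_uncertain = FALSE) {
  need <- c("mass_kg", "status", "direct_date", "earliest_bp", "latest_bp")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    mp_stop(paste("records missing columns:", paste(miss, collapse = ", ")),
            "invalid_config")
  }
  ok_status <- records$status == "accepted" |
    (include_uncertain & records$status == "uncertain")
  ok_mass <- records$mass_kg >= min_mass_kg
  ok_date <- records$direct_date
  # interval [latest, earliest] must intersect [young, old]; ends inclusive
  ok_window <- records$earliest_bp >= window[2] & records$latest_bp <= window[1] &
    records$earliest_bp >= records$latest_bp &
    pmin(records$earliest_bp, window[1]) >= pmax(records$latest_bp, window[2])
  keep <- ok_status & ok_mass & ok_date & ok_window
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) mp_warn("no species pass the filters", "empty_result")
  out
}

#' Clean raw occurrence records
#'
#' Drops, with logged reason codes: records at exactly (0, 0); captive
#' records; records on a continent where the species has no directly dated
#' site; and extant-range records of continentally (not globally) extinct
#' species. Nothing is dropped silently.
#'
#' @param points data frame: `species_id`, `x`, `y`, `continent`, and
#'   optional logical columns `captive` and `extant_range`.
#' @param dated_sites data frame `species_id`, `continent` of directly dated
#'   sites (defines the allowed continents per species); `NULL` disables the
#'   off-continent rule.
#' @param species optional species table with `species_id` and `scope`; the
#'   extant-range rule applies only to `scope == "continental"` species.
#' @return list: `points` (retained rows), `dropped` (rows plus a `reason`
#'   column).
#' @export
clean_occurrences <- function(points, dated_sites = NULL, species = NULL) {
  reason <- rep(NA_character_, nrow(points))
  zero <- points$x == 0 & points$y == 0
  reason[zero] <- "zero-coordinate"
  if (!is.null(points$captive)) {
    reason[is.na(reason) & points$captive] <- "captive"
  }
  if (!is.null(dated_sites)) {
    key <- paste(points$species_id, points$continent)
    allowed <- paste(dated_sites$species_id, dated_sites$continent)
    reason[is.na(reason) & !(key %in% allowed)] <- "off-continent"
  }
  if (!is.null(points$extant_range) && !is.null(species)) {
    cont_ext <- species$species_id[species$scope == "continental"]
    bad <- points$extant_range & points$species_id %in% cont_ext
    reason[is.na(reason) & bad] <- "extant-range"
  }
  keep <- is.na(reason)
  dropped <- points[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!keep]
  else dropped$reason <- character(0)
  list(points = points[keep, , drop = FALSE], dropped = dropped)
}

#' Snap occurrence points to analysis regions
#'
#' A point inside the lattice takes the region owning its cell. A point
#' outside (offshore) is snapped to the nearest region within
#' `snap_radius_km` — distance measured to the nearest owned cell centre —
#' emulating the relocation of coastal records to the nearest region to
#' account for glacial sea-level change. Beyond the radius the point is
#' dropped with a reason. Exact distance ties break deterministically to the
#' smallest region id.
#'
#' @param points data frame with `x`, `y` in km.
#' @param world a [generate_regions] result.
#' @param snap_radius_km maximum snap distance.
#' @return data frame: the input plus `region_id` (`NA` when dropped) and
#'   `snap_reason` (`"inside"`, `"snapped"`, `"beyond-radius"`).
#' @export
snap_to_nearest_region <- function(points, world, snap_radius_km = 50) {
  cfg <- world$cfg
  m <- world$membership
  nr <- nrow(m); nc <- ncol(m)
  cs <- cfg$cell_size_km
  cx <- (col(m) - 0.5) * cs
  cy <- (row(m) - 0.5) * cs
  ids <- as.vector(m); keep <- !is.na(ids)
  cell_x <- as.vector(cx)[keep]; cell_y <- as.vector(cy)[keep]
  cell_id <- ids[keep]

  region_id <- rep(NA_integer_, nrow(points))
  reason <- rep(NA_character_, nrow(points))
  for (i in seq_len(nrow(points))) {
    r <- floor(points$y[i] / cs) + 1
    c <- floor(points$x[i] / cs) + 1
    if (r >= 1 && r <= nr && c >= 1 && c <= nc && !is.na(m[r, c])) {
      region_id[i] <- m[r, c]
      reason[i] <- "inside"
    } else {
      d2 <- (cell_x - points$x[i])^2 + (cell_y - points$y[i])^2
      dmin <- sqrt(min(d2))
      if (dmin <= snap_radius_km) {
        cand <- cell_id[sqrt(d2) <= dmin + 1e-9]
        region_id[i] <- min(cand)  # tie-break: smallest region id
        reason[i] <- "snapped"
      } else {
        reason[i] <- "beyond-radius"
      }
    }
  }
  out <- points
  out$region_id <- region_id
  out$snap_reason <- reason
  out
}

#' Fill gaps in a species range
#'
#' Corrects collection-effort and taphonomic gaps in a fossil range on the
#' region adjacency graph, three rules:
#' (i) discontinuous ranges: occupied components are connected along the
#' least-cost path, where entering a region costs the absolute difference
#' between its environmental score and the mean score of the directly
#' occupied regions ("the path that best reflects the conditions where
#' specimens were recovered");
#' (ii) holes: an unoccupied region all of whose neighbours are occupied is
#' filled, iterated to a fixed point;
#' (iii) peripheral regions are filled only when explicitly listed — there
#' is no automatic edge heuristic.
#' Direct presences are never modified; every fill is recorded as
#' `"interpolated"`. Components that cannot be connected (disconnected
#' adjacency) are left unfilled and logged.
#'
#' @param presence logical/0-1 vector over regions (named or positional).
#' @param adjacency symmetric list of neighbour indices per region.
#' @param region_env per-region environmental score used for path costs.
#' @param peripheral integer vector of region indices to fill under rule
#'   (iii).
#' @return list: `filled` (0/1 vector), `provenance` (`"direct"`,
#'   `"interpolated"` or `""`), `log` (character).
#' @export
fill_gaps <- function(presence, adjacency, region_env, peripheral = integer(0)) {
  n <- length(adjacency)
  pres <- as.integer(presence) == 1L
  if (length(pres) != n || length(region_env) != n) {
    mp_stop("presence/env length must match adjacency", "invalid_config")
  }
  prov <- ifelse(pres, "direct", "")
  logs <- character(0)
  env_ref <- mean(region_env[pres])
  cost <- abs(region_env - env_ref)

  # rule (i): connect occupied components by least-cost paths
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(adjacency[[i]])) cbind(i, adjacency[[i]]) else NULL
  }))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- cost[edges[, 2]] + 1e-12  # cost of entering target
  repeat {
    occ <- which(pres)
    comp <- component_labels(occ, adjacency, pres)
    if (max(comp) <= 1) break
    # cheapest path between any two distinct components
    best <- NULL
    reps <- split(occ, comp)
    dmat <- igraph::distances(g, v = occ, to = occ, mode = "out")
    for (a in seq_along(reps)) for (b in seq_along(reps)) {
      if (a >= b) next
      sub <- dmat[match(reps[[a]], occ), match(reps[[b]], occ), drop = FALSE]
      if (all(!is.finite(sub))) next
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      cand <- list(from = reps[[a]][ij[1]], to = reps[[b]][ij[2]],
                   d = min(sub))
      if (is.null(best) || cand$d < best$d) best <- cand
    }
    if (is.null(best)) {
      logs <- c(logs, sprintf("unreachable components left unfilled (%d)",
                              max(comp)))
      break
    }
    path <- igraph::shortest_paths(g, from = best$from, to = best$to,
                                   mode = "out")$vpath[[1]]
    path <- as.integer(path)
    newly <- setdiff(path, which(pres))
    pres[newly] <- TRUE
    prov[newly] <- "interpolated"
    if (length(newly)) {
      logs <- c(logs, sprintf("rule i: filled %s",
                              paste(newly, collapse = ",")))
    }
  }

  # rule (ii): holes, to a fixed point
  repeat {
    holes <- which(!pres & vapply(adjacency, function(nb) {
      length(nb) > 0 && all(pres[nb])
    }, TRUE))
    if (!length(holes)) break
    pres[holes] <- TRUE
    prov[holes] <- "interpolated"
    logs <- c(logs, sprintf("rule ii: filled %s", paste(holes, collapse = ",")))
  }

  # rule (iii): explicit peripheral list only
  extra <- setdiff(peripheral, which(pres))
  if (length(extra)) {
    pres[extra] <- TRUE
    prov[extra] <- "interpolated"
    logs <- c(logs, sprintf("rule iii: filled %s", paste(extra, collapse = ",")))
  }
  list(filled = as.integer(pres), provenance = prov, log = logs)
}

## connected-component labels of the occupied subgraph
component_labels <- function(occ, adjacency, pres) {
  lab <- integer(length(occ)); names(lab) <- occ
  cur <- 0L
  for (s in occ) {
    if (lab[as.character(s)] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[as.character(v)] > 0) next
      lab[as.character(v)] <- cur
      nb <- adjacency[[v]]
      nb <- nb[pres[nb] & lab[as.character(nb)] == 0]
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Per-region extinct counts and per-continent tallies
#'
#' Column sums of the (filled) presence matrix give the cumulative number of
#' extinct species per region. The continental tally counts a species once
#' per continent where it occupies at least one region, so tallies across
#' continents may sum to more than the global species count.
#'
#' @param presence binary species x region matrix (columns named/ordered by
#'   `regions$region_id`).
#' @param regions region data frame with `region_id` and `continent`.
#' @return list: `region_counts` (named integer vector), `continent_tally`
#'   (named integer vector).
#' @export
extinction_counts <- function(presence, regions) {
  if (ncol(presence) != nrow(regions)) {
    mp_stop("presence columns must match regions", "invalid_config")
  }
  region_counts <- colSums(presence)
  names(region_counts) <- regions$region_id
  conts <- sort(unique(regions$continent))
  tally <- vapply(conts, function(ct) {
    cols <- which(regions$continent == ct)
    sum(rowSums(presence[, cols, drop = FALSE]) > 0)
  }, 0L)
  names(tally) <- conts
  list(region_counts = region_counts, continent_tally = tally)
}

#' Read / write the species-table and presence CSV schemas
#'
#' Plain-CSV interchange mirroring the curated supplementary schemas: the
#' species table (`name, mass_kg, status, direct_date, earliest_bp,
#' latest_bp, scope`) and the long-format presence table (`species_id,
#' region_id, provenance`).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_species_csv <- function(path) {
  if (!file.exists(path)) mp_stop(paste("file not found:", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "mass_kg", "status", "direct_date", "earliest_bp",
            "latest_bp", "scope")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    mp_stop(paste("species CSV missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  }
  if (!"species_id" %in% names(df)) df$species_id <- sprintf("sp%03d", seq_len(nrow(df)))
  df$direct_date <- as.logical(df$direct_date)
  df
}

#' @rdname read_species_csv
#' @export
read_presence_csv <- function(path) {
  if (!file.exists(path)) mp_stop(paste("file not found:", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("species_id", "region_id", "provenance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    mp_stop(paste("presence CSV missing columns:", paste(miss, collapse = ", ")),
            "schema_error")
  }
  df
}

#' Long-format presence table to a binary matrix
#'
#' @param presence_df long table from [read_presence_csv()].
#' @param region_ids full ordered vector of region ids (columns of the
#'   output).
#' @return list: binary `presence` matrix and character `provenance` matrix.
#' @export
presence_long_to_matrix <- function(presence_df, region_ids) {
  sp <- sort(unique(presence_df$species_id))
  m <- matrix(0L, length(sp), length(region_ids),
              dimnames = list(sp, region_ids))
  prov <- matrix("", length(sp), length(region_ids),
                 dimnames = list(sp, region_ids))
  ri <- match(presence_df$region_id, region_ids)
  si <- match(presence_df$species_id, sp)
  if (anyNA(ri)) mp_stop("presence table names unknown regions", "schema_error")
  m[cbind(si, ri)] <- 1L
  prov[cbind(si, ri)] <- presence_df$provenance
  list(presence = m, provenance = prov)
}
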