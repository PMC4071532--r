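mk_records <- function(mass, status = "accepted", direct = TRUE,
                       earliest = 50000, latest = 20000) {
  n <- max(lengths(list(mass, status, direct, earliest, latest)))
  data.frame(species_id = sprintf("sp%02d", seq_len(n)),
             mass_kg = rep_len(mass, n), status = rep_len(status, n),
             direct_date = rep_len(direct, n),
             earliest_bp = rep_len(earliest, n),
             latest_bp = rep_len(latest, n))
}

test_that("mass threshold is inclusive and monotone in min_mass", {
  rec <- mk_records(c(9.9, 10, 44, 200, 8))
  expect_equal(nrow(filter_species(rec, min_mass_kg = 10)), 3)
  expect_equal(nrow(filter_species(rec, min_mass_kg = 44)), 2)
  # non-increasing in min_mass over a sweep
  set.seed(2)
  rec2 <- mk_records(rlnorm(60, log(50), 1.5))
  counts <- vapply(c(5, 10, 20, 44, 100),
                   function(m) nrow(filter_species(rec2, min_mass_kg = m)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("window, dating and status rules filter as specified", {
  # dated only 900 BP: lost within the last millennium, excluded
  rec <- mk_records(100, earliest = 900, latest = 500)
  expect_warning(out <- filter_species(rec), class = "empty_result")
  expect_equal(nrow(out), 0)
  # no direct date excluded
  rec2 <- mk_records(100, direct = FALSE)
  expect_warning(expect_equal(nrow(filter_species(rec2)), 0))
  # uncertain only enters with the flag
  rec3 <- mk_records(c(100, 100), status = c("accepted", "uncertain"))
  expect_equal(nrow(filter_species(rec3)), 1)
  expect_equal(nrow(filter_species(rec3, include_uncertain = TRUE)), 2)
  # interval straddling the old edge is excluded (not fully dated in window)
  rec4 <- mk_records(100, earliest = 170000, latest = 140000)
  expect_warning(expect_equal(nrow(filter_species(rec4)), 0))
})

test_that("occurrence cleaning drops with logged reasons and conserves counts", {
  pts <- data.frame(
    species_id = c("a", "a", "a", "b", "b"),
    x = c(0, 10, 20, 30, 40), y = c(0, 1, 2, 3, 4),
    continent = c(1, 1, 2, 1, 1),
    captive = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    extant_range = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  dated <- data.frame(species_id = c("a", "b"), continent = c(1, 1))
  species <- data.frame(species_id = c("a", "b"),
                        scope = c("global", "continental"))
  out <- clean_occurrences(pts, dated, species)
  expect_equal(nrow(out$points) + nrow(out$dropped), nrow(pts))
  expect_equal(nrow(out$points), 1)
  expect_setequal(out$dropped$reason,
                  c("zero-coordinate", "captive", "off-continent",
                    "extant-range"))
  expect_equal(out$dropped$reason[out$dropped$x == 0], "zero-coordinate")
})

test_that("points snap to containing region, nearest within radius, or drop", {
  w <- tiny_world(seed = 3, n_regions = 12, grid = c(4, 6))
  cs <- w$cfg$cell_size_km
  # point inside the cell of region m[2,2]
  inside <- data.frame(x = 1.5 * cs, y = 1.5 * cs)
  out <- snap_to_nearest_region(inside, w)
  expect_equal(out$region_id, w$membership[2, 2])
  expect_equal(out$snap_reason, "inside")
  # 10 km offshore of the left edge: snaps to the nearest edge region
  off <- data.frame(x = -10, y = 1.5 * cs)
  out2 <- snap_to_nearest_region(off, w, snap_radius_km = 100)
  expect_equal(out2$region_id, w$membership[2, 1])
  expect_equal(out2$snap_reason, "snapped")
  # far offshore beyond the radius: dropped
  far <- data.frame(x = -500, y = 1.5 * cs)
  out3 <- snap_to_nearest_region(far, w, snap_radius_km = 50)
  expect_true(is.na(out3$region_id))
  expect_equal(out3$snap_reason, "beyond-radius")
  # equidistant tie breaks to the smallest region id: a 1 x 8 strip of
  # single-cell regions, point offshore exactly between two cell centres
  w2 <- generate_regions(world_config(n_regions = 8, grid_shape = c(1, 8),
                                      n_continents = 1, seed = 1))
  cs2 <- w2$cfg$cell_size_km
  tie <- data.frame(x = cs2, y = -10)  # equidistant to cells 1 and 2
  out4 <- snap_to_nearest_region(tie, w2, snap_radius_km = 200)
  expect_equal(out4$region_id, min(w2$membership[1, 1:2]))
})

test_that("gap filling implements rules i and ii with provenance", {
  # chain A-B-C with A, C present: B interpolated (rule i)
  adj <- list(2L, c(1L, 3L), 2L)
  res <- fill_gaps(c(1, 0, 1), adj, region_env = c(0.5, 0.5, 0.5))
  expect_equal(res$filled, c(1, 1, 1))
  expect_equal(res$provenance, c("direct", "interpolated", "direct"))
  # hole with all neighbours occupied (rule ii)
  # star: centre 1 connected to 2,3,4; 2,3,4 mutually connected in a ring
  adj2 <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  res2 <- fill_gaps(c(0, 1, 1, 1), adj2, region_env = rep(0.2, 4))
  expect_equal(res2$filled, c(1, 1, 1, 1))
  expect_equal(res2$provenance[1], "interpolated")
  # rule iii only with an explicit list
  res3 <- fill_gaps(c(1, 0, 1), adj, region_env = c(0.5, 0.5, 0.5),
                    peripheral = integer(0))
  expect_equal(sum(res3$filled), 3)  # rule i fills B anyway on the chain
  adj4 <- list(2L, 1L)
  res4 <- fill_gaps(c(1, 0), adj4, region_env = c(0.1, 0.9),
                    peripheral = 2L)
  expect_equal(res4$filled, c(1, 1))
  expect_equal(res4$provenance[2], "interpolated")
})

test_that("least-cost connection matches exhaustive path enumeration", {
  # two corridors between components {1} and {5}: via 2 (one hop) or via
  # 3,4 (two hops); env makes the longer corridor cheaper. Node 6 dangles
  # off 2 so 2 is not later filled as a hole.
  adj <- list(c(2L, 3L), c(1L, 5L, 6L), c(1L, 4L), c(3L, 5L), c(2L, 4L),
              2L)
  pres <- c(1, 0, 0, 0, 1, 0)
  env <- c(0.5, 0.9, 0.52, 0.48, 0.5, 0.5)
  res <- fill_gaps(pres, adj, env)
  oracle_cost <- abs(env - mean(env[pres == 1]))
  best <- brute_best_path(adj, oracle_cost, from_set = 1L, to_set = 5L)
  expect_setequal(which(res$filled == 1), sort(unique(c(1L, best$path))))
  expect_true(all(c(3, 4) %in% which(res$filled == 1)))
  expect_false(2 %in% which(res$filled == 1))
  # randomized graphs: rule-i path cost equals oracle best cost
  set.seed(21)
  for (rep in 1:10) {
    n <- 8
    adj_r <- lapply(1:n, function(i) sort(unique(c(
      ifelse(i == 1, n, i - 1), ifelse(i == n, 1, i + 1)))))
    for (extra in 1:3) {
      ij <- sample(n, 2)
      adj_r[[ij[1]]] <- sort(unique(c(adj_r[[ij[1]]], ij[2])))
      adj_r[[ij[2]]] <- sort(unique(c(adj_r[[ij[2]]], ij[1])))
    }
    pres_r <- rep(0, n); pres_r[c(1, 5)] <- 1
    env_r <- runif(n)
    res_r <- fill_gaps(pres_r, adj_r, env_r)
    # nodes filled by rule i are recorded in the log
    rule1 <- res_r$log[startsWith(res_r$log, "rule i:")]
    path_nodes <- as.integer(unlist(strsplit(sub("rule i: filled ", "",
                                                 rule1), ",")))
    cost_r <- abs(env_r - mean(env_r[c(1, 5)]))
    best_r <- brute_best_path(adj_r, cost_r, from_set = 1L, to_set = 5L)
    got_cost <- sum(cost_r[path_nodes]) + cost_r[5]
    expect_equal(got_cost, best_r$cost, tolerance = 1e-9)
  }
})

test_that("filling is monotone and idempotent for rules i-ii", {
  w <- tiny_world(seed = 5, n_regions = 16, grid = c(4, 6))
  set.seed(5)
  env <- runif(16)
  pres <- as.integer(seq_len(16) %in% sample(16, 5))
  res <- fill_gaps(pres, w$adjacency, env)
  expect_true(all(res$filled >= pres))  # monotone
  res2 <- fill_gaps(res$filled, w$adjacency, env)
  expect_equal(res2$filled, res$filled)  # idempotent
  # provenance accounting
  expect_equal(sum(res$provenance == "direct"), sum(pres))
  expect_equal(sum(res$provenance != ""), sum(res$filled))
})

test_that("extinct counts per region and per continent tally correctly", {
  regions <- data.frame(region_id = 1:4, continent = c(1, 1, 2, 2))
  pres <- rbind(sp1 = c(1, 1, 0, 0),
                sp2 = c(1, 0, 1, 0),   # present on both continents
                sp3 = c(1, 0, 0, 0))
  out <- extinction_counts(pres, regions)
  expect_equal(unname(out$region_counts), c(3, 1, 1, 0))
  # sp2 counts on both continents; tallies may sum over the species count
  expect_equal(unname(out$continent_tally), c(3, 1))
  expect_gte(sum(out$continent_tally), nrow(pres))
  # empty region reports 0 extinctions
  expect_equal(unname(out$region_counts[4]), 0)
})

test_that("species and presence CSV schemas round-trip", {
  w <- tiny_world(seed = 1)
  sp <- generate_species_table(w, n_species = 12, seed = 2)
  sp_path <- tempfile(fileext = ".csv"); on.exit(unlink(sp_path), add = TRUE)
  write.csv(sp$species, sp_path, row.names = FALSE)
  rd <- read_species_csv(sp_path)
  expect_equal(rd$name, sp$species$name)
  expect_equal(rd$mass_kg, sp$species$mass_kg, tolerance = 1e-9)
  # presence long form
  idx <- which(sp$presence == 1, arr.ind = TRUE)
  long <- data.frame(species_id = rownames(sp$presence)[idx[, 1]],
                     region_id = colnames(sp$presence)[idx[, 2]],
                     provenance = "direct")
  pr_path <- tempfile(fileext = ".csv"); on.exit(unlink(pr_path), add = TRUE)
  write.csv(long, pr_path, row.names = FALSE)
  back <- presence_long_to_matrix(read_presence_csv(pr_path),
                                  colnames(sp$presence))
  expect_equal(unname(back$presence[rownames(sp$presence), ]),
               unname(sp$presence))
})
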