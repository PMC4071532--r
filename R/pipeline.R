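#' End-to-end run configuration
#'
#' All defaults mirror the primary analysis: >= 10 kg species, interpolated
#' ranges, the LGM-to-present epoch contrast, 4-nearest-neighbour spatial
#' weights, 500 km correlogram classes. Every sensitivity toggle (mass
#' threshold, uncertain species, interpolation off, epoch pair, climate as
#' categories) is addressable from here.
#'
#' @param mode `"synthetic"` (internal generator) or `"real"` (CSV/grid
#'   inputs via `paths`).
#' @param epoch_pair `"lgm-present"` or `"lig-lgm"`.
#' @param min_mass_kg 10 or 44.
#' @param include_uncertain logical sensitivity toggle.
#' @param interpolation logical; fill range gaps.
#' @param climate_as_categories logical; re-express climate scores as k-means
#'   classes.
#' @param alpha_impact significance gate of the richness correction.
#' @param alpha_lump contrast threshold of the ordinal category lumping.
#' @param k spatial-weight neighbour count.
#' @param class_width_km correlogram distance-class width.
#' @param n_perm correlogram permutations.
#' @param seed integer master seed.
#' @param world_args list of overrides passed to [world_config()].
#' @param dgp a [dgp_params()].
#' @param paths named list of input paths (real mode).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       epoch_pair = c("lgm-present", "lig-lgm"),
                       min_mass_kg = 10, include_uncertain = FALSE,
                       interpolation = TRUE, climate_as_categories = FALSE,
                       alpha_impact = 0.10, alpha_lump = 0.05,
                       k = 4, class_width_km = 500, n_perm = 999,
                       seed = 1, world_args = list(), dgp = dgp_params(),
                       paths = list()) {
  mode <- match.arg(mode)
  epoch_pair <- match.arg(epoch_pair)
  if (!min_mass_kg %in% c(10, 44)) {
    mp_stop("min_mass_kg must be 10 or 44", "invalid_config")
  }
  if (mode == "real") {
    for (p in unlist(paths)) {
      if (!file.exists(p)) {
        mp_stop(paste("input path does not exist:", p), "invalid_config")
      }
    }
  }
  structure(list(mode = mode, epoch_pair = epoch_pair,
                 min_mass_kg = min_mass_kg,
                 include_uncertain = include_uncertain,
                 interpolation = interpolation,
                 climate_as_categories = climate_as_categories,
                 alpha_impact = alpha_impact, alpha_lump = alpha_lump,
                 k = k, class_width_km = class_width_km, n_perm = n_perm,
                 seed = as.integer(seed), world_args = world_args,
                 dgp = dgp, paths = paths),
            class = "run_config")
}

## epoch separations in years: LGM ca 21 kyr BP, LIG ca 130 kyr BP
epoch_years <- function(epoch_pair) {
  switch(epoch_pair, "lgm-present" = 21000, "lig-lgm" = 109000,
         mp_stop("unknown epoch pair", "invalid_config"))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: climate (epoch-pair fields, anomaly/gradient/velocity,
#' regional aggregation, standardization), ranges (species filters,
#' gap-filled presences, extinct counts), richness (human-impact correction,
#' extinction proportions), models (candidate enumeration, arcsine fits,
#' AIC selection, quasi-binomial check, nested F tests), spatial (SAR error
#' model on the best combined spec, correlograms of GLM residuals and SAR
#' innovations). Synthetic mode generates all inputs; the modelled
#' extinction response is the one simulated by the data-generating process,
#' while the species-table branch exercises the curation stages and is
#' reported alongside.
#'
#' @param config a [run_config()].
#' @param out optional output directory; when given, result tables are
#'   written as CSV with a provenance header and a run log.
#' @return a `pipeline_result` list; see components in the examples.
#' @export
run_pipeline <- function(config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "real") {
    mp_stop("real mode requires externally supplied tables; synthetic mode is the tested path",
            "invalid_config")
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  ## --- world ---------------------------------------------------------
  wargs <- utils::modifyList(list(seed = config$seed), config$world_args)
  cfg <- do.call(world_config, wargs)
  world <- generate_regions(cfg)
  note("world: %d regions, %d continents, seed %d", nrow(world$regions),
       cfg$n_continents, config$seed)

  ## --- climate -------------------------------------------------------
  years <- epoch_years(config$epoch_pair)
  climate <- list()
  scores <- data.frame(region_id = world$regions$region_id)
  vars <- list(temperature = list(trend = c(25, -5), noise = 3,
                                  delta = c(-2, -14)),
               precipitation = list(trend = c(2000, 300), noise = 250,
                                    delta = c(-100, -600)))
  for (v in names(vars)) {
    pr <- vars[[v]]
    pair <- generate_epoch_pair(cfg, epochs = c("present", "lgm"),
                                smoothness_km = 300, r = 0.9,
                                delta = pr$delta,
                                seed = derive_seed(config$seed,
                                                   match(v, names(vars))),
                                trend_range = pr$trend, noise_sd = pr$noise,
                                variable = v)
    anom <- compute_anomaly(pair[[1]], pair[[2]])
    grad <- spatial_gradient(pair[[1]])
    vel <- velocity_surface(anom, grad, years = years)
    a_mean <- aggregate_to_regions(anom, world$membership, "mean")
    v_mean <- aggregate_to_regions(vel, world$membership, "mean")
    v_range <- aggregate_to_regions(vel, world$membership, "range")
    pref <- if (v == "temperature") "T" else "P"
    scores[[paste0(pref, "_anom")]] <- standardize_scores(a_mean)
    scores[[paste0(pref, "_vel")]] <- standardize_scores(v_mean)
    scores[[paste0(pref, "_vel_range")]] <- v_range
    climate[[v]] <- list(pair = pair, anomaly = anom, gradient = grad,
                         velocity = vel)
  }
  if (config$climate_as_categories) {
    for (colv in c("T_anom", "T_vel", "P_anom", "P_vel")) {
      scores[[colv]] <- as.numeric(
        kmeans_classes(scores[[colv]], k = 4,
                       seed = derive_seed(config$seed, 91)) - 1) / 3
    }
    note("climate: scores re-expressed as 4 k-means categories")
  }
  note("climate: %s contrast over %d yr", config$epoch_pair, years)

  ## --- extinction response (data-generating process) ----------------
  W <- knn_weights(cbind(world$regions$centroid_x_km,
                         world$regions$centroid_y_km), k = config$k)
  dgp_out <- generate_extinctions(world, ta_std = scores$T_anom,
                                  params = config$dgp,
                                  seed = derive_seed(config$seed, 7), W = W)

  ## --- species-table branch (curation stages) ------------------------
  sp <- generate_species_table(world, seed = derive_seed(config$seed, 13))
  accepted <- filter_species(sp$species, min_mass_kg = config$min_mass_kg,
                             include_uncertain = config$include_uncertain)
  note("ranges: %d of %d species pass filters (>= %g kg)", nrow(accepted),
       nrow(sp$species), config$min_mass_kg)
  pres <- sp$presence[accepted$species_id, , drop = FALSE]
  prov <- sp$provenance[accepted$species_id, , drop = FALSE]
  if (config$interpolation) {
    for (s in rownames(pres)) {
      filled <- fill_gaps(pres[s, ], world$adjacency, scores$T_anom)
      pres[s, ] <- filled$filled
      prov[s, ] <- ifelse(filled$provenance == "", prov[s, ],
                          filled$provenance)
    }
    note("ranges: gap filling applied (rules i-ii)")
  }
  counts <- extinction_counts(pres, world$regions)

  ## --- richness correction -------------------------------------------
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(derive_seed(config$seed, 17)))
  rt <- data.frame(
    region_id = world$regions$region_id,
    extant_large = pmax(dgp_out$total_species - dgp_out$extinct_count, 0L),
    small_richness = pmax(
      1L, as.integer(round_half_up(stats::rlnorm(nrow(world$regions),
                                                 log(80), 0.4)))),
    human_impact = stats::runif(nrow(world$regions)),
    continent = world$regions$continent
  )
  fits_rich <- fit_extant_model(rt)
  rt <- estimate_potential_richness(fits_rich, rt,
                                    alpha = config$alpha_impact)
  note("richness: corrected continents: %s",
       paste(names(fits_rich)[vapply(fits_rich, function(f)
         !is.na(f$impact_p) && f$impact_p <= config$alpha_impact, TRUE)],
         collapse = ", ") %||% "none")
  ok <- dgp_out$extinct_count + rt$estimated_extant > 0
  if (any(!ok)) note("richness: %d regions with undefined proportion excluded",
                     sum(!ok))
  prop <- extinction_proportion(dgp_out$extinct_count[ok],
                                rt$estimated_extant[ok])

  ## --- model data ----------------------------------------------------
  mdata <- data.frame(
    region_id = world$regions$region_id[ok],
    prop_extinct = prop,
    T_anom = scores$T_anom[ok], T_vel = scores$T_vel[ok],
    P_anom = scores$P_anom[ok], P_vel = scores$P_vel[ok],
    hominin5 = factor(world$regions$hominin[ok], levels = hominin_classes()),
    hominin3 = lump_archaic(world$regions$hominin[ok])
  )
  arrival <- c("Homo-origin" = 300, "Archaic-early" = 120, "Archaic-late" = 60,
               "Archaic-peripheral" = 45, "Hsapiens-only" = 15)  # kyr BP scale
  mdata$arrival_time <- arrival[as.character(mdata$hominin5)]

  climate_fits <- lapply(enumerate_candidates("climate"),
                         fit_arcsine_glm, data = mdata)
  sel_climate <- aic_select(climate_fits)
  hominin_fits <- lapply(enumerate_candidates("hominin"),
                         fit_arcsine_glm, data = mdata)
  sel_hominin <- aic_select(hominin_fits)
  combined_specs <- enumerate_candidates("combined",
                                         best_climate = sel_climate$fit$spec,
                                         best_hominin = sel_hominin$fit$spec)
  combined_fits <- lapply(combined_specs, fit_arcsine_glm, data = mdata)
  sel_combined <- aic_select(c(combined_fits,
                               list(sel_climate$fit, sel_hominin$fit)))
  note("models: best climate [%s], best hominin [%s], best combined [%s]",
       format(sel_climate$fit$spec), format(sel_hominin$fit$spec),
       format(sel_combined$fit$spec))
  quasi_check <- fit_quasibinomial_glm(sel_combined$fit$spec, mdata)
  f_vs_climate <- if (!identical(sel_combined$fit, sel_climate$fit) &&
                      all(colnames(sel_climate$fit$X) %in%
                            colnames(sel_combined$fit$X))) {
    f_test_nested(sel_climate$fit, sel_combined$fit)
  } else NULL
  f_vs_hominin <- if (!identical(sel_combined$fit, sel_hominin$fit) &&
                      all(colnames(sel_hominin$fit$X) %in%
                            colnames(sel_combined$fit$X))) {
    f_test_nested(sel_hominin$fit, sel_combined$fit)
  } else NULL
  lump <- lump_hominin_categories(arcsine_transform(mdata$prop_extinct),
                                  mdata$hominin5, alpha = config$alpha_lump)

  ## --- spatial -------------------------------------------------------
  coords <- cbind(world$regions$centroid_x_km,
                  world$regions$centroid_y_km)[ok, , drop = FALSE]
  Wok <- knn_weights(coords, k = config$k)
  sar <- sar_error_fit(sel_combined$fit$X, sel_combined$fit$y, Wok)
  cor_glm <- correlogram(sel_combined$fit$residuals, coords,
                         class_width_km = config$class_width_km,
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 29))
  cor_sar <- correlogram(sar$innovations, coords,
                         class_width_km = config$class_width_km,
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 31))
  note("spatial: lambda = %.3f, pseudo-R2 = %.3f", sar$lambda, sar$pseudo_r2)

  result <- structure(
    list(config = config, world = world, climate = climate, scores = scores,
         dgp = dgp_out, species = sp$species, accepted = accepted,
         presence = pres, provenance = prov, counts = counts,
         richness = rt, model_data = mdata,
         selection = list(climate = sel_climate, hominin = sel_hominin,
                          combined = sel_combined),
         quasibinomial_check = quasi_check,
         f_tests = list(vs_climate = f_vs_climate, vs_hominin = f_vs_hominin),
         lumping = lump, sar = sar,
         correlograms = list(glm = cor_glm, sar = cor_sar),
         log = log),
    class = "pipeline_result"
  )
  if (!is.null(out)) write_result_bundle(result, out)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

provenance_header <- function(config) {
  c(sprintf("# megapast %s", as.character(utils::packageVersion("megapast"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config: mode=%s epoch=%s min_mass=%g interp=%s k=%d width=%g",
            config$mode, config$epoch_pair, config$min_mass_kg,
            config$interpolation, config$k, config$class_width_km))
}

write_csv_prov <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write the result bundle of a pipeline run
#'
#' CSV tables (with provenance headers), the SAR fit report, both
#' correlograms and the run log, into `out`.
#'
#' @param result a `pipeline_result`.
#' @param out output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_result_bundle <- function(result, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  sc <- result$scores
  clim <- sc[, c("region_id", "T_anom", "T_vel", "P_anom", "P_vel",
                 "T_vel_range", "P_vel_range")]
  names(clim) <- c("region_id", "score_T_anom", "score_T_vel",
                   "score_P_anom", "score_P_vel", "velocity_range_T",
                   "velocity_range_P")
  write_csv_prov(clim, file.path(out, "region_climate.csv"), cfg)
  write_csv_prov(result$model_data, file.path(out, "model_data.csv"), cfg)
  write_csv_prov(result$richness, file.path(out, "richness.csv"), cfg)
  counts_df <- data.frame(region_id = names(result$counts$region_counts),
                          extinct_count = as.integer(result$counts$region_counts))
  write_csv_prov(counts_df, file.path(out, "extinct_counts.csv"), cfg)
  sar <- result$sar
  sar_df <- data.frame(
    term = c(names(sar$coefficients), "lambda", "sigma2", "logLik", "AIC",
             "pseudo_R2"),
    estimate = c(sar$coefficients, sar$lambda, sar$sigma2, sar$loglik,
                 sar$aic, sar$pseudo_r2),
    sd = c(sar$se, sar$lambda_se, rep(NA, 4)),
    Z = c(sar$z, rep(NA, 5)),
    p = c(sar$p, rep(NA, 5)))
  write_csv_prov(sar_df, file.path(out, "sar_fit.csv"), cfg)
  write_csv_prov(as.data.frame(result$correlograms$glm),
                 file.path(out, "correlogram_glm.csv"), cfg)
  write_csv_prov(as.data.frame(result$correlograms$sar),
                 file.path(out, "correlogram_sar.csv"), cfg)
  write_csv_prov(result$selection$climate$table,
                 file.path(out, "aic_climate.csv"), cfg)
  write_csv_prov(result$selection$combined$table,
                 file.path(out, "aic_combined.csv"), cfg)
  writeLines(result$log, file.path(out, "run_log.txt"))
  invisible(out)
}
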