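#' Fit the per-continent extant-richness model
#'
#' Quasi-likelihood GLM with logit link and variance `mu (1 - mu)` modelling
#' extant large-mammal richness as a function of small-mammal richness and a
#' human-impact index, fitted separately per continent. Because the
#' `mu (1 - mu)` variance requires a response in (0, 1), large richness is
#' expressed as a fraction of the regional species pool
#' `S = extant_large + small_richness`; the pool scale is carried with each
#' fit so predictions can be mapped back to counts.
#'
#' @param table data frame with columns `region_id`, `extant_large`,
#'   `small_richness`, `human_impact`, `continent`.
#' @param continent optional: fit only this continent.
#' @return named list (one per continent) of `extant_model` objects: the
#'   `glm`, pool sizes `S`, `impact_p` (human-impact p-value),
#'   `impact_range`, region ids.
#' @export
fit_extant_model <- function(table, continent = NULL) {
  need <- c("region_id", "extant_large", "small_richness", "human_impact",
            "continent")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    mp_stop(paste("richness table missing:", paste(miss, collapse = ", ")),
            "invalid_config")
  }
  conts <- if (is.null(continent)) sort(unique(table$continent)) else continent
  fits <- list()
  for (ct in conts) {
    d <- table[table$continent == ct, , drop = FALSE]
    if (nrow(d) < 5) {
      mp_stop(sprintf("continent %s has < 5 regions", ct), "invalid_config")
    }
    S <- d$extant_large + d$small_richness
    if (any(S <= 0)) {
      mp_stop("regional species pool must be positive", "invalid_config")
    }
    d$pool_frac <- d$extant_large / S
    form <- pool_frac ~ small_richness + human_impact
    dropped <- character(0)
    for (v in c("small_richness", "human_impact")) {
      if (stats::var(d[[v]]) == 0) dropped <- c(dropped, v)
    }
    if (length(dropped)) {
      mp_warn(paste("zero-variance covariates dropped:",
                    paste(dropped, collapse = ", ")), "degenerate_design")
      form <- stats::update(form,
        paste(". ~ . -", paste(dropped, collapse = " - ")))
    }
    fit <- suppressWarnings(
      stats::glm(form, family = stats::quasibinomial(), data = d, weights = S)
    )
    if (!fit$converged) {
      mp_stop(sprintf("IRLS failed to converge for continent %s", ct),
              "convergence_error")
    }
    sm <- summary(fit)
    impact_p <- if ("human_impact" %in% rownames(sm$coefficients)) {
      sm$coefficients["human_impact", 4]
    } else NA_real_
    fits[[as.character(ct)]] <- structure(
      list(glm = fit, continent = ct, S = S, region_id = d$region_id,
           impact_p = impact_p,
           impact_range = range(d$human_impact), data = d,
           dropped = dropped),
      class = "extant_model"
    )
  }
  if (!is.null(continent) && length(fits) == 1) fits[[1]] else fits
}

#' Estimate potential extant richness at minimal human impact
#'
#' For continents where the human-impact coefficient is significant at
#' `alpha`, extant richness is re-predicted with every region's human impact
#' set to the lowest value recorded within that continent (so the prediction
#' stays inside the fitted range); otherwise the observed richness is kept.
#' Predicted pool fractions are mapped back to counts with the region's pool
#' scale and rounded half-up.
#'
#' @param fits result of [fit_extant_model()] (list over continents).
#' @param table the richness table the fits were built from.
#' @param alpha significance gate; default 0.10 so borderline continents
#'   (p just above 0.05) are corrected.
#' @return `table` with columns `estimated_extant` and `corrected` (logical)
#'   appended.
#' @export
estimate_potential_richness <- function(fits, table, alpha = 0.10) {
  if (inherits(fits, "extant_model")) {
    fits <- stats::setNames(list(fits), as.character(fits$continent))
  }
  table$estimated_extant <- table$extant_large
  table$corrected <- FALSE
  for (ct in names(fits)) {
    f <- fits[[ct]]
    rows <- which(table$continent == f$continent)
    if (is.na(f$impact_p) || f$impact_p > alpha) next
    min_imp <- f$impact_range[1]
    if (min_imp < f$impact_range[1] || min_imp > f$impact_range[2]) {
      mp_stop("prediction outside fitted human-impact range", "range_error")
    }
    nd <- f$data
    nd$human_impact <- min_imp
    phat <- stats::predict(f$glm, newdata = nd, type = "response")
    est <- as.integer(round_half_up(phat * f$S))
    idx <- match(f$region_id, table$region_id[rows])
    table$estimated_extant[rows[idx]] <- est
    table$corrected[rows[idx]] <- TRUE
  }
  table
}

#' Proportion of the regional fauna that went extinct
#'
#' `extinct / (extinct + estimated_extant)`: extinction expressed against
#' the total of extinct plus (potential) extant species, controlling for
#' natural richness gradients and region area. Regions with neither extinct
#' nor extant species have no defined proportion and raise a classed error
#' so the caller can exclude and log them.
#'
#' @param extinct extinct-species count (>= 0).
#' @param estimated_extant estimated extant richness (>= 0).
#' @return proportion(s) in `[0, 1]`.
#' @export
extinction_proportion <- function(extinct, estimated_extant) {
  if (any(extinct < 0) || any(estimated_extant < 0)) {
    mp_stop("counts must be nonnegative", "invalid_config")
  }
  tot <- extinct + estimated_extant
  if (any(tot == 0)) {
    mp_stop("both counts zero: proportion undefined", "undefined_proportion")
  }
  extinct / tot
}
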