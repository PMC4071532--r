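#' Arcsine-square-root transform of a proportion
#'
#' Variance-stabilizing map `y = arcsin(sqrt(p))` from `[0, 1]` onto
#' `[0, pi/2]`. Used so a halving of a regional fauna carries the same weight
#' whether the fauna is large or small.
#'
#' @param p proportions in `[0, 1]`.
#' @return transformed values.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    mp_stop("proportions must lie in [0, 1]", "domain_error")
  }
  asin(sqrt(p))
}

#' Inverse arcsine-square-root transform
#'
#' `p = sin^2(y)` with `y` clamped to the invertible interval `[0, pi/2]`;
#' fitted values below 0 map to proportion 0, above `pi/2` to 1.
#'
#' @param y values on the arcsine scale.
#' @return proportions in `[0, 1]`.
#' @export
inverse_arcsine <- function(y) {
  sin(pmin(pmax(y, 0), pi / 2))^2
}

#' Candidate model specification
#'
#' A predictor set for the extinction-proportion models: any subset of the
#' four standardized climate scores (`T_anom`, `T_vel`, `P_anom`, `P_vel`),
#' an optional hominin coding (`"hominin5"`, `"hominin3"`, or the
#' `"arrival_time"` covariate), and optionally hominin-by-climate
#' interactions. The anomaly and the velocity of the same climate variable
#' are never allowed together (they are derived from each other and
#' collinear).
#'
#' @param climate character subset of
#'   `c("T_anom", "T_vel", "P_anom", "P_vel")`.
#' @param hominin `NULL` or one of `"hominin5"`, `"hominin3"`,
#'   `"arrival_time"`.
#' @param interactions logical; include hominin x climate interactions.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(climate = character(), hominin = NULL,
                       interactions = FALSE) {
  vars <- c("T_anom", "T_vel", "P_anom", "P_vel")
  if (length(setdiff(climate, vars))) {
    mp_stop("unknown climate term", "invalid_config")
  }
  if (("T_anom" %in% climate && "T_vel" %in% climate) ||
      ("P_anom" %in% climate && "P_vel" %in% climate)) {
    mp_stop("anomaly and velocity of the same variable cannot co-occur",
            "invalid_config")
  }
  if (!is.null(hominin) &&
      !hominin %in% c("hominin5", "hominin3", "arrival_time")) {
    mp_stop("unknown hominin coding", "invalid_config")
  }
  if (interactions && (is.null(hominin) || !length(climate))) {
    mp_stop("interactions require both hominin and climate terms",
            "invalid_config")
  }
  structure(list(climate = sort(climate), hominin = hominin,
                 interactions = isTRUE(interactions)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  parts <- c(x$climate, x$hominin,
             if (x$interactions) paste0(x$hominin, ":climate"))
  if (!length(parts)) parts <- "1"
  paste(parts, collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n"); invisible(x)
}

#' Model formula of a candidate spec
#'
#' Builds the fitting formula against a data frame holding columns
#' `prop_extinct`, the climate scores, `hominin5`/`hominin3` factors and
#' `arrival_time`.
#'
#' @param spec a [model_spec].
#' @param response response column name.
#' @return a formula.
#' @export
spec_formula <- function(spec, response = "prop_extinct") {
  rhs <- spec$climate
  if (!is.null(spec$hominin)) rhs <- c(rhs, spec$hominin)
  if (spec$interactions) {
    rhs <- c(rhs, paste(spec$hominin, spec$climate, sep = ":"))
  }
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

n_spec_terms <- function(spec) {
  length(spec$climate) + (!is.null(spec$hominin)) +
    spec$interactions * length(spec$climate)
}

#' Gaussian least squares on the arcsine scale
#'
#' The "GLM with arcsine square-root transformation": ordinary (equal-weight)
#' least squares with identity link on `arcsin(sqrt(p))`. This is the only
#' reading with a defined AIC, which is what the candidate comparison needs.
#' The AIC convention is the full Gaussian log-likelihood including its
#' `2*pi` terms, with the error variance counted as a parameter — identical
#' to `stats::AIC` on an `lm` fit:
#' `AIC = n log(2 pi RSS/n) + n + 2 (p + 1)`.
#'
#' @param formula model formula whose response is a proportion in `[0, 1]`
#'   (transformed internally), or a [model_spec].
#' @param data data frame.
#' @return object of class `arcsine_fit`: the `lm` fit plus `aic`, `r2`,
#'   overall F statistic against the intercept-only model (`f`, `df1`,
#'   `df2`, `f_p`), `n`, `n_par`.
#' @export
fit_arcsine_glm <- function(formula, data) {
  spec <- NULL
  if (inherits(formula, "model_spec")) {
    spec <- formula
    formula <- spec_formula(spec)
  }
  mf <- stats::model.frame(formula, data)
  p_raw <- stats::model.response(mf)
  y <- arcsine_transform(p_raw)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    mp_stop(paste("rank-deficient design; aliased:",
                  paste(bad, collapse = ", ")), "design_error")
  }
  fit <- stats::lm.fit(X, y)
  n <- length(y); p <- ncol(X)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / n
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  aic <- -2 * loglik + 2 * (p + 1)
  if (p > 1) {
    f <- ((tss - rss) / (p - 1)) / (rss / (n - p))
    f_p <- stats::pf(f, p - 1, n - p, lower.tail = FALSE)
  } else {
    f <- NA_real_; f_p <- NA_real_
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * rss / (n - p))
  tstat <- fit$coefficients / se
  structure(
    list(coefficients = fit$coefficients, se = se, t = tstat,
         p = 2 * stats::pt(-abs(tstat), n - p),
         residuals = as.numeric(fit$residuals),
         fitted = as.numeric(y - fit$residuals), y = y,
         rss = rss, sigma2 = sigma2, loglik = loglik, aic = aic,
         r2 = if (tss > 0) 1 - rss / tss else NA_real_,
         f = f, df1 = p - 1, df2 = n - p, f_p = f_p,
         n = n, n_par = p, X = X, formula = formula, spec = spec),
    class = "arcsine_fit"
  )
}

#' @export
print.arcsine_fit <- function(x, ...) {
  cat("Gaussian least squares on arcsine-sqrt proportions\n")
  print(round(data.frame(estimate = x$coefficients, se = x$se,
                         t = x$t, p = x$p), 4))
  cat(sprintf("R2 = %.3f, AIC = %.2f, F(%d, %d) = %.3f (p = %.3g), n = %d\n",
              x$r2, x$aic, x$df1, x$df2, x$f, x$f_p, x$n))
  invisible(x)
}

#' Quasi-binomial GLM on raw proportions
#'
#' Logit link, variance `mu (1 - mu)`, dispersion estimated by Pearson
#' chi-squared over residual df; the distribution-free check on the
#' arcsine-scale analysis. No AIC is defined under quasi-likelihood.
#' Zero-variance covariates are dropped with a warning rather than
#' propagating `NA` coefficients.
#'
#' @param formula model formula (response a proportion in `[0, 1]`) or a
#'   [model_spec].
#' @param data data frame.
#' @param weights optional prior weights (e.g. species totals); equal by
#'   default.
#' @return object of class `quasibin_fit` wrapping the `glm`: coefficients,
#'   dispersion-scaled `se`, `t`, `p`, `dispersion`, `dropped` covariates.
#' @export
fit_quasibinomial_glm <- function(formula, data, weights = NULL) {
  if (inherits(formula, "model_spec")) formula <- spec_formula(formula)
  tms <- stats::terms(formula, data = data)
  vars <- attr(tms, "term.labels")
  dropped <- character(0)
  for (v in vars) {
    if (v %in% names(data) && is.numeric(data[[v]]) &&
        stats::var(data[[v]]) == 0) {
      dropped <- c(dropped, v)
    }
  }
  if (length(dropped)) {
    mp_warn(paste("zero-variance covariates dropped:",
                  paste(dropped, collapse = ", ")), "degenerate_design")
    formula <- stats::update(formula,
      paste(". ~ . -", paste(dropped, collapse = " - ")))
  }
  env <- new.env(parent = globalenv())
  assign("..data", data, envir = env)
  assign("..w", weights, envir = env)
  environment(formula) <- env
  fit <- suppressWarnings(stats::glm(formula, family = stats::quasibinomial(),
                                     data = data, weights = ..w))
  if (!fit$converged) {
    mp_stop("quasi-binomial IRLS failed to converge", "convergence_error")
  }
  sm <- summary(fit)
  structure(
    list(glm = fit, coefficients = stats::coef(fit),
         se = sm$coefficients[, 2], t = sm$coefficients[, 3],
         p = sm$coefficients[, 4], dispersion = sm$dispersion,
         dropped = dropped, n = stats::nobs(fit)),
    class = "quasibin_fit"
  )
}

#' Enumerate candidate model specifications
#'
#' Three candidate families: climate-only (every non-empty subset of the four
#' climate scores in which the anomaly and velocity of a variable never
#' co-occur — per variable the choice is none/anomaly/velocity, i.e.
#' `3 * 3 - 1 = 8` specs), hominin-only (five-level coding, lumped
#' three-level coding, and the modern-human arrival-time covariate), and
#' combined (a climate spec and a hominin coding plus their interactions;
#' defaults to the crossing of the supplied best specs).
#'
#' @param mode `"climate"`, `"hominin"`, or `"combined"`.
#' @param best_climate,best_hominin for `mode = "combined"`: the selected
#'   [model_spec]s from the single-family stages.
#' @return list of [model_spec]s.
#' @export
enumerate_candidates <- function(mode = c("climate", "hominin", "combined"),
                                 best_climate = NULL, best_hominin = NULL) {
  mode <- match.arg(mode)
  if (mode == "climate") {
    choice_T <- list(character(0), "T_anom", "T_vel")
    choice_P <- list(character(0), "P_anom", "P_vel")
    out <- list()
    for (ct in choice_T) for (cp in choice_P) {
      cl <- c(ct, cp)
      if (length(cl)) out[[length(out) + 1]] <- model_spec(climate = cl)
    }
    return(out)
  }
  if (mode == "hominin") {
    return(list(model_spec(hominin = "hominin5"),
                model_spec(hominin = "hominin3"),
                model_spec(hominin = "arrival_time")))
  }
  if (is.null(best_climate) || is.null(best_hominin)) {
    mp_stop("combined mode needs best_climate and best_hominin specs",
            "invalid_config")
  }
  list(model_spec(climate = best_climate$climate,
                  hominin = best_hominin$hominin, interactions = TRUE),
       model_spec(climate = best_climate$climate,
                  hominin = best_hominin$hominin, interactions = FALSE))
}

#' Select the best model by AIC
#'
#' Minimal AIC wins; exact ties break toward the fit with fewer parameters.
#' All fits must share the same response vector — AICs on different
#' responses are not comparable.
#'
#' @param fits list of `arcsine_fit` (or `sar_fit`) objects.
#' @return list: `best` (index), `fit`, `table` (data frame ranked by AIC
#'   with spec labels, AIC, delta-AIC, n_par).
#' @export
aic_select <- function(fits) {
  if (!length(fits)) mp_stop("no fits supplied", "invalid_config")
  ys <- lapply(fits, function(f) f$y)
  for (yy in ys[-1]) {
    if (!isTRUE(all.equal(ys[[1]], yy))) {
      mp_stop("fits do not share a response vector; AIC not comparable",
              "comparison_error")
    }
  }
  aic <- vapply(fits, function(f) f$aic, 0.0)
  npar <- vapply(fits, function(f) f$n_par, 0.0)
  ord <- order(aic, npar)
  best <- ord[1]
  lab <- vapply(seq_along(fits), function(i) {
    s <- fits[[i]]$spec
    if (!is.null(s)) format(s) else paste("model", i)
  }, "")
  tab <- data.frame(model = lab[ord], aic = aic[ord],
                    delta_aic = aic[ord] - aic[best], n_par = npar[ord])
  list(best = best, fit = fits[[best]], table = tab)
}

#' Merge ordered categories by adjacent contrasts
#'
#' Operationalizes the ordinal analysis of the five hominin classes: fit the
#' response on the current grouping, test every contrast between adjacent
#' group means, merge the least-significant adjacent pair whose p-value
#' exceeds `alpha`, and iterate to a fixed point. On the study system this
#' recovers three groups: the origin region, the three archaic classes
#' merged, and the modern-human-only region.
#'
#' @param y response vector (arcsine-scale proportions).
#' @param category factor or character with the ordered categories; order
#'   taken from factor levels (or [hominin_classes()] order for characters).
#' @param alpha contrast significance threshold; adjacent groups whose
#'   difference has `p > alpha` are merged.
#' @return list: `groups` (integer group id per original level, increasing
#'   along the order), `coding` (factor per observation), `n_groups`,
#'   `history` of merges.
#' @export
lump_hominin_categories <- function(y, category, alpha = 0.05) {
  if (!is.factor(category)) {
    lev <- if (all(unique(category) %in% hominin_classes())) {
      intersect(hominin_classes(), unique(category))
    } else sort(unique(category))
    category <- factor(category, levels = lev)
  }
  lev <- levels(category)
  if (length(lev) < 2) mp_stop("need >= 2 categories", "invalid_config")
  counts <- table(category)
  if (any(counts < 2)) {
    mp_stop(paste("categories with < 2 observations:",
                  paste(names(counts)[counts < 2], collapse = ", ")),
            "sparse_category_error")
  }
  groups <- seq_along(lev)
  history <- list()
  repeat {
    g <- factor(groups[as.integer(category)], levels = sort(unique(groups)))
    k <- nlevels(g)
    if (k == 1) break
    X <- stats::model.matrix(~ g - 1)
    fit <- stats::lm.fit(X, y)
    n <- length(y)
    s2 <- sum(fit$residuals^2) / (n - k)
    m <- fit$coefficients
    sizes <- colSums(X)
    ps <- numeric(k - 1)
    for (j in seq_len(k - 1)) {
      se <- sqrt(s2 * (1 / sizes[j] + 1 / sizes[j + 1]))
      tstat <- (m[j + 1] - m[j]) / se
      ps[j] <- 2 * stats::pt(-abs(tstat), n - k)
    }
    worst <- which.max(ps)
    if (ps[worst] <= alpha) break
    gl <- sort(unique(groups))
    from <- gl[worst + 1]; into <- gl[worst]
    groups[groups == from] <- into
    groups <- match(groups, sort(unique(groups)))  # renumber 1..k-1
    history[[length(history) + 1]] <- list(merged = c(into, from), p = ps[worst])
  }
  names(groups) <- lev
  list(groups = groups,
       coding = factor(groups[as.integer(category)]),
       n_groups = length(unique(groups)), history = history)
}

#' Partial F test of nested least-squares fits
#'
#' `F = [(RSS_small - RSS_big)/Dk] / [RSS_big/df_big]`, with `Dk` the number
#' of added parameters. Both numerator and denominator degrees of freedom
#' are reported explicitly.
#'
#' @param fit_small,fit_big nested `arcsine_fit` objects sharing the same
#'   response.
#' @return list: `f`, `df1`, `df2`, `p`.
#' @export
f_test_nested <- function(fit_small, fit_big) {
  if (!isTRUE(all.equal(fit_small$y, fit_big$y))) {
    mp_stop("fits do not share a response", "nesting_error")
  }
  if (fit_big$n_par < fit_small$n_par ||
      !all(colnames(fit_small$X) %in% colnames(fit_big$X))) {
    mp_stop("small model is not nested in big model", "nesting_error")
  }
  df1 <- fit_big$n_par - fit_small$n_par
  df2 <- fit_big$n - fit_big$n_par
  if (df1 == 0) return(list(f = 0, df1 = 0, df2 = df2, p = 1))
  f <- ((fit_small$rss - fit_big$rss) / df1) / (fit_big$rss / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}
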