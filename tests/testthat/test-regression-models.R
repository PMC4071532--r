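test_that("arcsine transform hits its closed-form anchors", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(0.25), pi / 6, tolerance = 1e-12)
  expect_equal(arcsine_transform(1), pi / 2, tolerance = 1e-12)
  expect_error(arcsine_transform(1.2), class = "domain_error")
  expect_error(arcsine_transform(-0.1), class = "domain_error")
  # inverse round trip and clamping
  p <- seq(0, 1, by = 0.05)
  expect_equal(inverse_arcsine(arcsine_transform(p)), p, tolerance = 1e-12)
  expect_equal(inverse_arcsine(-0.3), 0)
  expect_equal(inverse_arcsine(2), 1)
})

test_that("arcsine fit equals OLS normal equations with documented AIC", {
  # intercept-only on transformed y: coefficient = mean, RSS as stated
  d <- data.frame(prop_extinct = sin(c(0.2, 0.4, 0.6))^2)
  fit <- fit_arcsine_glm(prop_extinct ~ 1, d)
  expect_equal(unname(fit$coefficients), 0.4, tolerance = 1e-12)
  expect_equal(fit$rss, 0.08, tolerance = 1e-12)
  # documented AIC convention matches stats::AIC on the same lm
  set.seed(4)
  d2 <- data.frame(prop_extinct = runif(30, 0.05, 0.95), x = rnorm(30))
  fit2 <- fit_arcsine_glm(prop_extinct ~ x, d2)
  lm2 <- lm(asin(sqrt(prop_extinct)) ~ x, data = d2)
  expect_equal(fit2$aic, AIC(lm2), tolerance = 1e-9)
  expect_equal(unname(fit2$coefficients), unname(coef(lm2)), tolerance = 1e-12)
  # normal-equations oracle to 1e-10
  X <- cbind(1, d2$x)
  y <- asin(sqrt(d2$prop_extinct))
  beta_or <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit2$coefficients), drop(beta_or), tolerance = 1e-10)
  # rank deficiency is a classed error naming the column
  d2$x2 <- d2$x
  expect_error(fit_arcsine_glm(prop_extinct ~ x + x2, d2),
               class = "design_error")
})

test_that("overall F equals hand ANOVA on a two-group design", {
  y <- c(0.1, 0.15, 0.12, 0.45, 0.5, 0.42)
  d <- data.frame(prop_extinct = sin(y)^2, g = rep(c("a", "b"), each = 3))
  fit <- fit_arcsine_glm(prop_extinct ~ g, d)
  expect_equal(fit$f, hand_anova_f(y, d$g), tolerance = 1e-9)
  expect_equal(fit$df1, 1)
  expect_equal(fit$df2, 4)
})

test_that("arcsine-scale coefficient recovery within 2 SE in >= 93/100", {
  w <- default_world(1)
  ta <- default_ta(w)
  beta <- dgp_params()$beta
  lump <- lump_archaic(w$regions$hominin)
  hits <- matrix(NA, 100, 6)
  for (s in 1:100) {
    set.seed(s)
    X <- reference_design(w, ta)
    y <- drop(X %*% beta) + rnorm(229, sd = 0.1)
    d <- data.frame(prop_extinct = inverse_arcsine(y), hominin3 = lump,
                    T_anom = ta)
    fit <- fit_arcsine_glm(prop_extinct ~ hominin3 * T_anom, d)
    # map fitted coefficients back to the reference parameterization
    est <- fit$coefficients
    se <- fit$se
    # model.matrix order: intercept, AC, HS, TA, AC:TA, HS:TA
    hits[s, ] <- abs(est - beta[c(1, 3, 2, 4, 6, 5)]) <= 2 * se
  }
  expect_true(all(colSums(hits) >= 93))
})

test_that("quasi-binomial fit reproduces logit differences and consistency", {
  d <- data.frame(prop_extinct = rep(c(0.25, 0.5), each = 6),
                  x = rep(c(0, 1), each = 6))
  fit <- fit_quasibinomial_glm(prop_extinct ~ x, d)
  expect_equal(unname(fit$coefficients["x"]), qlogis(0.5) - qlogis(0.25),
               tolerance = 1e-7)
  # constant response: zero slope
  d0 <- data.frame(prop_extinct = rep(0.5, 10), x = rnorm(10))
  fit0 <- fit_quasibinomial_glm(prop_extinct ~ x, d0)
  expect_equal(unname(fit0$coefficients["x"]), 0, tolerance = 1e-8)
  # monotone effect: same coefficient signs as the arcsine fit
  set.seed(12)
  d1 <- data.frame(x = runif(80))
  d1$prop_extinct <- plogis(-1 + 2 * d1$x + rnorm(80, sd = 0.3))
  fa <- fit_arcsine_glm(prop_extinct ~ x, d1)
  fq <- fit_quasibinomial_glm(prop_extinct ~ x, d1)
  expect_equal(sign(unname(fa$coefficients[2])),
               sign(unname(fq$coefficients["x"])))
})

test_that("climate candidate enumeration is exactly the 8 legal subsets", {
  specs <- enumerate_candidates("climate")
  expect_length(specs, 8)
  labels <- vapply(specs, format, "")
  expect_length(unique(labels), 8)
  for (sp in specs) {
    expect_false("T_anom" %in% sp$climate && "T_vel" %in% sp$climate)
    expect_false("P_anom" %in% sp$climate && "P_vel" %in% sp$climate)
    expect_gte(length(sp$climate), 1)
  }
  # brute force: 3 * 3 - 1 legal non-empty subsets
  legal <- 0
  for (t_choice in 0:2) for (p_choice in 0:2) {
    if (t_choice + p_choice > 0) legal <- legal + 1
  }
  expect_equal(length(specs), legal)
  # illegal spec construction rejected
  expect_error(model_spec(climate = c("T_anom", "T_vel")),
               class = "invalid_config")
  # combined mode carries hominin x climate interactions
  comb <- enumerate_candidates("combined",
                               best_climate = model_spec("T_anom"),
                               best_hominin = model_spec(hominin = "hominin3"))
  expect_true(any(vapply(comb, function(s) s$interactions, TRUE)))
})

test_that("AIC selection takes the minimum with parsimony tie-break", {
  mk <- function(aic, npar, y = 1:5) {
    structure(list(aic = aic, n_par = npar, y = y), class = "arcsine_fit")
  }
  sel <- aic_select(list(mk(10, 3), mk(12, 2)))
  expect_equal(sel$best, 1)
  sel2 <- aic_select(list(mk(10, 3), mk(10, 2)))
  expect_equal(sel2$best, 2)
  expect_error(aic_select(list(mk(10, 3), mk(11, 2, y = 2:6))),
               class = "comparison_error")
})

test_that("AIC selects the true hominin-only model in most simulations", {
  # scaled-down in-suite version (full 200-seed run lives in acceptance)
  w <- default_world(1)
  ta <- default_ta(w)
  lump <- lump_archaic(w$regions$hominin)
  wins <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    y <- 0.3 + 0.5 * (lump == "Hsapiens-only") + 0.25 * (lump == "Archaic-combined") +
      rnorm(229, sd = 0.12)
    d <- data.frame(prop_extinct = inverse_arcsine(y), hominin3 = lump,
                    hominin5 = factor(w$regions$hominin,
                                      levels = hominin_classes()),
                    arrival_time = rnorm(229),
                    T_anom = ta, T_vel = runif(229),
                    P_anom = runif(229), P_vel = runif(229))
    fits <- c(lapply(enumerate_candidates("climate"), fit_arcsine_glm, data = d),
              list(fit_arcsine_glm(prop_extinct ~ hominin3, d)))
    sel <- aic_select(fits)
    if (sel$best == length(fits)) wins <- wins + 1
  }
  expect_gte(wins, 36)
})

test_that("ordinal lumping merges and splits as the contrasts dictate", {
  set.seed(31)
  lev <- hominin_classes()
  g <- factor(rep(lev, each = 40), levels = lev)
  mu <- c(0.10, 0.30, 0.30, 0.30, 0.55)
  y <- rnorm(200, mean = mu[as.integer(g)], sd = 0.05)
  out <- lump_hominin_categories(y, g, alpha = 0.05)
  expect_equal(out$n_groups, 3)
  expect_equal(unname(out$groups), c(1, 2, 2, 2, 3))
  # all-equal means collapse to one group
  y0 <- rnorm(200, mean = 0.3, sd = 0.05)
  out0 <- lump_hominin_categories(y0, g, alpha = 0.05)
  expect_equal(out0$n_groups, 1)
  # alpha = 1 keeps all five groups (no p-value can exceed 1)
  out1 <- lump_hominin_categories(y, g, alpha = 1)
  expect_equal(out1$n_groups, 5)
  # sparse category errors
  g_sparse <- factor(c(rep(lev[1], 5), lev[2], rep(lev[3], 5)),
                     levels = lev[1:3])
  expect_error(lump_hominin_categories(rnorm(11), g_sparse),
               class = "sparse_category_error")
})

test_that("nested F matches hand partial-F arithmetic and null uniformity", {
  # hand-built 6-point example with one added predictor
  d <- data.frame(prop_extinct = sin(c(0.30, 0.35, 0.28, 0.60, 0.55, 0.62))^2,
                  x = c(0, 0, 0, 1, 1, 1), z = c(1, 2, 3, 1, 2, 3))
  small <- fit_arcsine_glm(prop_extinct ~ x, d)
  big <- fit_arcsine_glm(prop_extinct ~ x + z, d)
  ft <- f_test_nested(small, big)
  y <- asin(sqrt(d$prop_extinct))
  rss_s <- sum(resid(lm(y ~ d$x))^2)
  rss_b <- sum(resid(lm(y ~ d$x + d$z))^2)
  f_hand <- ((rss_s - rss_b) / 1) / (rss_b / 3)
  expect_equal(ft$f, f_hand, tolerance = 1e-10)
  expect_equal(ft$df1, 1); expect_equal(ft$df2, 3)
  # identical models: F = 0, p = 1
  ft0 <- f_test_nested(small, small)
  expect_equal(ft0$f, 0); expect_equal(ft0$p, 1)
  # adding pure noise: p uniform (KS at 0.01), scaled-down 300 reps
  set.seed(9)
  pvals <- replicate(300, {
    dd <- data.frame(prop_extinct = runif(25, 0.1, 0.9), x = rnorm(25),
                     noise = rnorm(25))
    f_test_nested(fit_arcsine_glm(prop_extinct ~ x, dd),
                  fit_arcsine_glm(prop_extinct ~ x + noise, dd))$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # non-nested rejected
  d3 <- data.frame(prop_extinct = runif(10, 0.2, 0.8), a = rnorm(10),
                   b = rnorm(10))
  expect_error(f_test_nested(fit_arcsine_glm(prop_extinct ~ a, d3),
                             fit_arcsine_glm(prop_extinct ~ b, d3)),
               class = "nesting_error")
})
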