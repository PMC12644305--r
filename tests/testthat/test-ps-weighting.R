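test_that("an intercept-only model returns the exposure prevalence", {
  e <- rep(c(1, 0), times = c(30, 70))
  fit <- fit_propensity_model(matrix(numeric(0), nrow = 100, ncol = 0), e)
  expect_equal(fit$ps, rep(0.3, 100), tolerance = 1e-8)
  expect_equal(fit$p_exposed, 0.3)
})

test_that("a single binary covariate reproduces levelwise exposure proportions", {
  set.seed(4)
  x <- rbinom(400, 1, 0.5)
  e <- rbinom(400, 1, ifelse(x == 1, 0.6, 0.25))
  fit <- fit_propensity_model(cbind(x = x), e)
  expect_equal(unique(round(fit$ps[x == 1], 10)),
               round(mean(e[x == 1]), 10))
  expect_equal(unique(round(fit$ps[x == 0], 10)),
               round(mean(e[x == 0]), 10))
})

test_that("propensity coefficients match glm and recover generator effects", {
  cfg <- sim_config(
    n_patients = 20000, seed = 21,
    latent_effects = list(severity = c(exposure = 0, outcome = 0),
                          frailty = c(exposure = 0, outcome = 0)),
    missing_rates = c(bmi = 0, ethnicity = 0, imd = 0))
  cohort <- generate_cohort(cfg)
  X <- hdps:::prespec_design(cohort)
  fit <- fit_propensity_model(X, cohort$exposure)
  ref <- glm(cohort$exposure ~ X, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  # recovery: every true non-zero effect within 2 SE
  truth <- hdps:::expand_effects(NULL, colnames(X),
                                 hdps:::default_exposure_effects())
  se <- summary(ref)$coefficients[-1, "Std. Error"]
  est <- coef(ref)[-1]
  expect_true(all(abs(est - truth) <= 2.5 * se))
})

test_that("separation is reported with the offending column named", {
  e <- rep(c(1, 0), each = 25)
  x <- cbind(sep_col = e, ok = rbinom(50, 1, 0.5))
  expect_error(fit_propensity_model(x, e), "sep_col")
})

test_that("collinear columns are dropped with a warning", {
  set.seed(5)
  x1 <- rbinom(200, 1, 0.4)
  X <- cbind(a = x1, b = x1)
  e <- rbinom(200, 1, plogis(-0.5 + x1))
  expect_warning(fit <- fit_propensity_model(X, e), "collinear")
  expect_equal(fit$dropped, "b")
  expect_length(fit$coef, 2L)
})

test_that("stabilized weights follow their closed form", {
  expect_equal(stabilized_weights(0.4, 1, p_exposed = 0.4), 1)
  expect_equal(stabilized_weights(0.2, 0, p_exposed = 0.4), 0.6 / 0.8)
  expect_error(stabilized_weights(c(0, 0.5), c(1, 0)), "exactly 0 or 1")
})

test_that("stabilized weights average 1 and preserve arm sizes on simulated data", {
  prep <- small_prep()
  ps <- fit_propensity_model(prep$X_prespec, prep$cohort$exposure)
  w <- stabilized_weights(ps$ps, prep$cohort$exposure)
  expect_lt(abs(mean(w) - 1), 0.02)
  e <- prep$cohort$exposure
  expect_lt(abs(sum(w[e == 1]) / sum(e == 1) - 1), 0.05)
  expect_lt(abs(sum(w[e == 0]) / sum(e == 0) - 1), 0.05)
})

test_that("common-support trimming performs interval arithmetic on PS ranges", {
  ps <- c(0.2, 0.5, 0.85, 0.9, 0.1, 0.5, 0.8)
  e <- c(1, 1, 1, 1, 0, 0, 0)
  tr <- trim_common_support(ps, e)
  expect_equal(tr$lower, 0.2)
  expect_equal(tr$upper, 0.8)
  expect_equal(unname(tr$n_excluded), c(2L, 1L))
  expect_false(tr$keep[3])
  # identical ranges -> nobody excluded
  tr2 <- trim_common_support(c(0.1, 0.9, 0.1, 0.9), c(1, 1, 0, 0))
  expect_true(all(tr2$keep))
  # one group inside the other -> inner range
  tr3 <- trim_common_support(c(0.4, 0.6, 0.1, 0.9), c(1, 1, 0, 0))
  expect_equal(c(tr3$lower, tr3$upper), c(0.4, 0.6))
  expect_error(trim_common_support(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
               "no common support")
})

test_that("re-trimming nests the bounds and erodes at most the boundary", {
  # exact idempotence when the bounds are attained in both groups
  ps <- c(0.2, 0.5, 0.8, 0.2, 0.5, 0.8, 0.1, 0.9)
  e <- c(1, 1, 1, 0, 0, 0, 0, 1)
  tr <- trim_common_support(ps, e)
  tr2 <- trim_common_support(ps[tr$keep], e[tr$keep])
  expect_true(all(tr2$keep))
  expect_equal(c(tr$lower, tr$upper), c(tr2$lower, tr2$upper))
  # with continuous scores the second pass stays nested and near-identity
  set.seed(8)
  ps <- runif(5000, 0.05, 0.95)
  e <- rbinom(5000, 1, ps)
  tr <- trim_common_support(ps, e)
  tr2 <- trim_common_support(ps[tr$keep], e[tr$keep])
  expect_gte(tr2$lower, tr$lower)
  expect_lte(tr2$upper, tr$upper)
  expect_lt(sum(!tr2$keep) / sum(tr$keep), 0.005)
})

test_that("binary SMD follows its closed form", {
  x <- c(rep(1, 400), rep(0, 600), rep(1, 200), rep(0, 800))
  e <- rep(c(1, 0), each = 1000)
  want <- 0.2 / sqrt((0.4 * 0.6 + 0.2 * 0.8) / 2)
  expect_equal(standardized_mean_difference(x, e), want, tolerance = 2e-3)
  expect_equal(standardized_mean_difference(rep(c(1, 0, 1, 0), 25),
                                            rep(c(1, 1, 0, 0), 25)), 0)
})

test_that("degenerate columns give 0 (identical) or Inf (disjoint)", {
  e <- rep(c(1, 0), each = 10)
  expect_equal(standardized_mean_difference(rep(1, 20), e), 0)
  expect_equal(standardized_mean_difference(e, e), Inf)
})

test_that("a two-level factor agrees with the binary formula", {
  set.seed(9)
  x <- rbinom(2000, 1, 0.35)
  e <- rbinom(2000, 1, plogis(-0.4 + 0.8 * x))
  w <- runif(2000, 0.5, 2)
  num <- standardized_mean_difference(x, e, w)
  fac <- standardized_mean_difference(factor(x, levels = 0:1), e, w)
  # the multi-category statistic uses population-form level variances, the
  # binary one the frequency-weight (n - 1) form; they agree up to that
  # finite-sample correction
  expect_equal(fac, num, tolerance = 1e-3)
})

test_that("weighting on the true PS model balances covariates below 0.1", {
  prep <- small_prep()
  ps <- fit_propensity_model(prep$X_prespec, prep$cohort$exposure)
  w <- stabilized_weights(ps$ps, prep$cohort$exposure)
  smds <- apply(prep$X_prespec, 2, standardized_mean_difference,
                exposure = prep$cohort$exposure, weights = w)
  expect_true(all(smds < 0.1))
})

test_that("PS density output covers both arms on a common grid", {
  set.seed(10)
  ps <- runif(300, 0.1, 0.9)
  e <- rbinom(300, 1, ps)
  d <- ps_density(ps, e, n = 64)
  expect_setequal(unique(d$arm), c("exposed", "unexposed"))
  expect_equal(nrow(d), 128L)
  expect_true(all(d$density >= 0))
})
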