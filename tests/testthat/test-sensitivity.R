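test_that("missing-data rules follow the declared conventions", {
  co <- data.frame(
    patient_id = 1:6, exposure = c(1, 0, 1, 0, 1, 0),
    bmi_cat = factor(c(NA, NA, NA, "obese", "normal", "underweight"),
                     levels = c("underweight", "normal", "overweight",
                                "obese")),
    ethnicity = factor(c("White", NA, "Black", "White", "White", "White"),
                       levels = c("White", "South Asian", "Black", "Mixed")),
    imd_quintile = factor(c("1", "2", NA, NA, "3", "5"),
                          levels = as.character(1:5)))
  out <- apply_missing_data_rules(co)
  expect_equal(nrow(out), 4L)
  expect_equal(attr(out, "n_imd_dropped"), 2L)
  expect_false(anyNA(out$bmi_cat))
  expect_true(all(out$bmi_cat[out$patient_id %in% 1:2] == "normal"))
  expect_true("Unknown" %in% levels(out$ethnicity))
  expect_equal(as.character(out$ethnicity[out$patient_id == 2]), "Unknown")
})

test_that("missing-data rules are the identity on complete data and error elsewhere", {
  sim <- small_sim()
  complete <- sim$cohort[!is.na(sim$cohort$bmi_cat) &
                           !is.na(sim$cohort$ethnicity) &
                           !is.na(sim$cohort$imd_quintile), ]
  out <- apply_missing_data_rules(complete)
  expect_equal(out$patient_id, complete$patient_id)
  expect_equal(attr(out, "n_imd_dropped"), 0L)
  bad <- complete
  bad$exposure[1] <- NA
  expect_error(apply_missing_data_rules(bad), "exposure")
})

test_that("k = 0 reproduces the hand-composed conventional pipeline", {
  sim <- small_sim()
  fit <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 0)
  # independent composition from the exported module operations
  co <- apply_missing_data_rules(sim$cohort)
  X <- hdps:::prespec_design_for(co, prespecified_covariate_names())
  ps <- fit_propensity_model(X, co$exposure)
  tr <- trim_common_support(ps$ps, co$exposure)
  e <- co$exposure[tr$keep]
  w <- stabilized_weights(ps$ps[tr$keep], e, p_exposed = mean(e))
  hr <- weighted_cox_hr(co$time_to_event[tr$keep], co$event[tr$keep], e, w)
  est <- effect_estimates(fit)
  expect_equal(est$point[est$estimand == "HR"], hr$estimate$point,
               tolerance = 1e-12)
  expect_null(fit$hdps)
  expect_identical(fit$primary, fit$conventional)
})

test_that("latent generator columns never influence estimation", {
  sim <- small_sim()
  blinded <- sim$cohort
  blinded$latent_severity <- 0
  blinded$latent_frailty <- 0
  f1 <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 25)
  f2 <- hdps_fit(blinded, sim$events, sim$maps, k = 25)
  expect_equal(effect_estimates(f1), effect_estimates(f2), tolerance = 1e-12)
  expect_equal(f1$scores, f2$scores, tolerance = 1e-12)
})

test_that("the cohort definitions include or exclude triple-therapy users", {
  sim <- small_sim()
  f_inc <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 0,
                    cohort_def = "include_triple")
  f_exc <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 0,
                    cohort_def = "exclude_triple")
  triple <- sim$cohort$exposure == 1 & sim$cohort$triple_therapy == 1
  expect_equal(f_exc$ns$n_triple_excluded, sum(triple))
  expect_equal(f_inc$ns$n_triple_excluded, 0L)
  # triple patients with missing IMD are dropped in both cohorts
  overlap <- sum(triple & is.na(sim$cohort$imd_quintile))
  expect_equal(f_inc$ns$n_analysis - f_exc$ns$n_analysis,
               sum(triple) - overlap)
})

test_that("excluded codes never reach the candidate covariates", {
  sim <- small_sim()
  fit <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 10)
  codes <- unique(fit$covariate_meta$code)
  expect_false(any(c("U07", "030200", "030101", "030102") %in% codes))
})

test_that("the k sweep matches individual fits and logs diagnostics", {
  sim <- small_sim()
  sweep <- hdps_k_sweep(sim$cohort, sim$events, sim$maps,
                        k_values = c(0, 25))
  fit25 <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 25)
  hr_sweep <- sweep$point[sweep$k == 25 & sweep$estimand == "HR"]
  hr_fit <- effect_estimates(fit25)
  hr_fit <- hr_fit$point[hr_fit$method == "hdps_25" &
                           hr_fit$estimand == "HR"]
  expect_equal(hr_sweep, hr_fit, tolerance = 1e-12)
  expect_true(all(c("max_weight", "ess_exposed") %in% names(sweep)))
})

test_that("the one-by-one trajectory keeps its bookkeeping contracts", {
  sim <- small_sim()
  traj <- one_by_one_trajectory(sim$cohort, sim$events, sim$maps,
                                max_rank = 5)
  expect_equal(traj$n_covariates, 1:5)
  expect_false(anyNA(traj$point))
  expect_true(all(traj$max_weight > 0))
  # step j = k agrees with a direct fit at that k
  fit3 <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 3)
  est <- effect_estimates(fit3)
  expect_equal(traj$point[3],
               est$point[est$method == "hdps_3" & est$estimand == "HR"],
               tolerance = 1e-12)
})

test_that("over-deep trajectories truncate with a warning", {
  cfg <- sim_config(n_patients = 800, n_confounder_codes = 2,
                    n_instrument_codes = 0, n_noise_codes = 0, seed = 13)
  sim <- simulate_hdps_data(cfg)
  expect_warning(traj <- one_by_one_trajectory(sim$cohort, sim$events,
                                               sim$maps, max_rank = 500),
                 "truncating")
  expect_lt(nrow(traj), 500)
})

test_that("estimates saturate once all informative covariates are included", {
  # only confounder codes in the pool: adding covariates beyond the
  # informative set must not move the estimate much
  cfg <- sim_config(n_patients = 8000, n_noise_codes = 0,
                    n_instrument_codes = 0, seed = 31)
  sim <- simulate_hdps_data(cfg)
  sweep <- hdps_k_sweep(sim$cohort, sim$events, sim$maps,
                        k_values = c(100, 150))
  hrs <- sweep$point[sweep$estimand == "HR"]
  expect_lt(abs(log(hrs[2] / hrs[1])), 0.2)
})

test_that("a dominant confounder produces its largest jump at rank 1", {
  hits <- vapply(1:8, function(s) {
    cfg <- sim_config(
      n_patients = 5000, seed = 1200 + s,
      n_confounder_codes = 1, n_instrument_codes = 0, n_noise_codes = 8,
      latent_effects = list(severity = c(exposure = 1, outcome = 1.2),
                            frailty = c(exposure = 0, outcome = 0)))
    sim <- simulate_hdps_data(cfg)
    traj <- one_by_one_trajectory(sim$cohort, sim$events, sim$maps,
                                  max_rank = 6)
    base <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 0)
    est0 <- effect_estimates(base)
    lhr <- c(log(est0$point[est0$estimand == "HR"]), log(traj$point))
    steps <- abs(diff(lhr))
    which.max(steps) == 1L
  }, TRUE)
  expect_gte(mean(hits), 0.75)
})

test_that("summary, coef, predict and plot methods work on a fitted analysis", {
  sim <- small_sim()
  fit <- hdps_fit(sim$cohort, sim$events, sim$maps, k = 10)
  s <- summary(fit)
  expect_s3_class(s, "summary.hdps_fit")
  expect_named(coef(fit), c("log_HR", "log_OR", "RD"))
  ps <- predict(fit, model = "conventional")
  expect_length(ps, fit$ns$n_analysis)
  co <- apply_missing_data_rules(sim$cohort)
  ps_new <- predict(fit, newdata = co[1:5, ], model = "conventional")
  expect_equal(ps_new, ps[1:5], tolerance = 1e-10)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_output(print(s))
})

test_that("rerunning the pipeline with one seed gives identical results", {
  cfg <- sim_config(n_patients = 1500, seed = 23)
  f1 <- run_analysis(cfg, k = 20)
  f2 <- run_analysis(cfg, k = 20)
  expect_identical(effect_estimates(f1), effect_estimates(f2))
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$balance, f2$balance)
})
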