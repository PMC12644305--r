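test_that("invalid configurations are rejected with the parameter named", {
  expect_error(sim_config(p_exposed_target = 1.2), "p_exposed_target")
  expect_error(sim_config(followup_days = 0), "followup_days")
  expect_error(sim_config(n_noise_codes = -1), "n_noise_codes")
  expect_error(sim_config(true_log_hr = Inf), "true_log_hr")
  expect_error(sim_config(latent_effects = list(
    severity = c(exposure = NaN, outcome = 0),
    frailty = c(exposure = 0, outcome = 0))), "severity")
  expect_error(sim_config(covariate_effects_exposure = c(past_asthma = Inf)),
               "covariate_effects_exposure")
})

test_that("the same seed reproduces cohort, events and maps exactly", {
  cfg <- sim_config(n_patients = 500, seed = 9)
  a <- simulate_hdps_data(cfg)
  b <- simulate_hdps_data(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$events, b$events)
  expect_identical(a$maps, b$maps)
})

test_that("marginal exposure prevalence hits its target at n = 10 000", {
  cfg <- sim_config(n_patients = 10000, seed = 3)
  cohort <- generate_cohort(cfg)
  expect_lt(abs(mean(cohort$exposure) - cfg$p_exposed_target), 0.05)
})

test_that("a fully null configuration gives equal outcome risk in both arms", {
  cfg <- sim_config(
    n_patients = 30000, seed = 5,
    latent_effects = list(severity = c(exposure = 0, outcome = 0),
                          frailty = c(exposure = 0, outcome = 0)),
    covariate_effects_exposure = 0, covariate_effects_outcome = 0)
  cohort <- generate_cohort(cfg)
  p1 <- mean(cohort$event[cohort$exposure == 1])
  p0 <- mean(cohort$event[cohort$exposure == 0])
  ptest <- prop.test(
    c(sum(cohort$event[cohort$exposure == 1]),
      sum(cohort$event[cohort$exposure == 0])),
    c(sum(cohort$exposure == 1), sum(cohort$exposure == 0)))
  expect_gt(ptest$p.value, 0.001)
  expect_lt(abs(p1 - p0), 0.01)
})

test_that("latent confounding biases the unadjusted hazard ratio upward", {
  # spec-level generator check: severity -> exposure +1 and -> outcome +1
  # with a true null must make the crude HR exceed 1 on average
  loghrs <- vapply(1:20, function(s) {
    cfg <- sim_config(
      n_patients = 20000, seed = 100 + s,
      latent_effects = list(severity = c(exposure = 1, outcome = 1),
                            frailty = c(exposure = 0, outcome = 0)))
    cohort <- generate_cohort(cfg)
    fit <- survival::coxph(
      survival::Surv(time_to_event, event) ~ exposure, data = cohort)
    unname(fit$coefficients)
  }, 0)
  expect_gt(mean(loghrs), 0)
  expect_gt(mean(loghrs) / (sd(loghrs) / sqrt(20)), 2)
})

test_that("with everything null the unadjusted log HR is centred on zero", {
  loghrs <- vapply(1:50, function(s) {
    cfg <- sim_config(
      n_patients = 4000, seed = 500 + s,
      latent_effects = list(severity = c(exposure = 0, outcome = 0),
                            frailty = c(exposure = 0, outcome = 0)),
      covariate_effects_exposure = 0, covariate_effects_outcome = 0)
    cohort <- generate_cohort(cfg)
    fit <- survival::coxph(
      survival::Surv(time_to_event, event) ~ exposure, data = cohort)
    unname(fit$coefficients)
  }, 0)
  expect_lt(abs(mean(loghrs)), 2 * sd(loghrs) / sqrt(50))
})

test_that("cohort fields respect their declared ranges", {
  sim <- small_sim()
  co <- sim$cohort
  cfg <- sim$config
  expect_true(all(co$time_to_event >= 1 & co$time_to_event <= cfg$followup_days))
  expect_true(all(co$event %in% 0:1))
  expect_true(all(co$triple_therapy[co$exposure == 0] == 0))
  expect_true(all(sim$events$event_date >= 1))
  expect_true(all(sim$events$dimension %in%
                    c("observation", "prescription", "hospitalisation")))
})

test_that("severity-proxy code counts increase with latent severity", {
  sim <- small_sim()
  reg <- sim$code_info
  sev_codes <- reg$harmonized[reg$role == "confounder" &
                                reg$latent == "severity" &
                                reg$dimension == "observation"]
  sev_raws <- unlist(lapply(sev_codes, function(h) paste0("SNO", h, c("a", "b"))))
  ev <- sim$events[sim$events$raw_code %in% sev_raws, ]
  cnt <- tabulate(ev$patient_id, nbins = nrow(sim$cohort))
  q <- quantile(sim$cohort$latent_severity, c(0.05, 0.95))
  lo <- cnt[sim$cohort$latent_severity <= q[1]]
  hi <- cnt[sim$cohort$latent_severity >= q[2]]
  expect_gt(mean(hi), mean(lo))
})

test_that("noise codes are equally prevalent in both arms", {
  cfg <- sim_config(n_patients = 20000, seed = 77)
  sim <- simulate_hdps_data(cfg)
  reg <- sim$code_info
  noise <- reg[reg$role == "noise", ]
  # per-code two-proportion checks across a sample of noise codes
  pvals <- vapply(seq(1, nrow(noise), by = 6), function(i) {
    raws <- hdps:::raw_aliases(noise$dimension[i], noise$harmonized[i])
    has <- sim$cohort$patient_id %in%
      sim$events$patient_id[sim$events$raw_code %in% raws]
    suppressWarnings(prop.test(table(sim$cohort$exposure, has))$p.value)
  }, 0)
  # no systematic association: at these sizes a real imbalance would give
  # vanishing p-values across the board
  expect_gt(max(pvals), 0.1)
  expect_gt(mean(pvals > 0.001), 0.8)
})

test_that("instrument codes vanish when configured to zero", {
  cfg <- sim_config(n_patients = 400, n_instrument_codes = 0, seed = 2)
  sim <- simulate_hdps_data(cfg)
  expect_false(any(sim$code_info$role == "instrument"))
  inst_prefixes <- c("SNOI", "DMD0401", "V")
  expect_false(any(grepl("^SNOI", sim$events$raw_code)))
  expect_false(any(grepl("^DMD0401", sim$events$raw_code)))
  expect_false(any(grepl("^V[0-9]", sim$events$raw_code)))
})

test_that("unmapped fraction removes the configured number of raw codes", {
  cfg0 <- sim_config(n_patients = 50, fraction_unmapped = 0, seed = 4)
  maps0 <- make_mapping_tables(cfg0)
  sim0 <- simulate_hdps_data(cfg0)
  obs_raws <- unique(sim0$events$raw_code[sim0$events$dimension == "observation"])
  expect_true(all(obs_raws %in% maps0$observation$source_code))

  # 20 confounder + 1 instrument + 29 noise codes -> 50 observation codes,
  # 2 raw aliases each = 100 raw codes; 10% unmapped -> 90 remain
  cfg1 <- sim_config(n_patients = 50, n_noise_codes = 29,
                     fraction_unmapped = 0.1, seed = 4)
  maps1 <- make_mapping_tables(cfg1)
  expect_identical(nrow(maps1$observation), 90L)
})

test_that("simulated tables round-trip through their CSV readers", {
  sim <- simulate_hdps_data(sim_config(n_patients = 200, seed = 8))
  dir <- withr::local_tempdir()
  files <- write_sim_data(sim, dir)
  co <- read_cohort(files[["cohort"]])
  ev <- read_code_events(files[["events"]])
  mp <- read_mapping_table(files[["map_observation"]])
  expect_equal(nrow(co), nrow(sim$cohort))
  for (nm in names(sim$cohort)) {
    if (is.factor(sim$cohort[[nm]]))
      expect_equal(as.character(co[[nm]]), as.character(sim$cohort[[nm]]),
                   info = nm)
    else
      expect_equal(co[[nm]], sim$cohort[[nm]], info = nm)
  }
  expect_equal(ev, sim$events)
  expect_equal(mp, sim$maps$observation)
})
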