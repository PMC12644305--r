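# Small shared fixtures, built once per test run.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_hdps_data(sim_config(n_patients = 3000, seed = 42))
    cache
  }
})

small_prep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- hdps:::prepare_hdps(sim$cohort, sim$events, sim$maps)
    }
    cache
  }
})

# A tiny hand-written event table spanning all three dimensions.
tiny_events <- function() {
  data.frame(
    patient_id = c(1L, 1L, 2L, 2L, 3L, 3L, 4L),
    dimension = c("observation", "observation", "observation",
                  "prescription", "prescription", "hospitalisation",
                  "hospitalisation"),
    raw_code = c("RAW1", "RAW2", "RAW1", "DRUG1", "DRUG2", "J449", "U071"),
    event_date = c(10L, 200L, 30L, 5L, 400L, 100L, 50L),
    stringsAsFactors = FALSE)
}

# Simulation-derived role keys ("dimension:code") for a dataset.
role_keys <- function(sim, role) {
  reg <- sim$code_info
  paste(reg$dimension[reg$role == role], reg$harmonized[reg$role == role],
        sep = ":")
}
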