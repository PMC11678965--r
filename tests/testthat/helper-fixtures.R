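# Shared fixtures: parameter sets and small cohort builders used across the
# module tests. Everything is generated in code; no stored data.

# fully deterministic generator settings (no noise, no jitter)
noiseless_params <- function(...) {
  group_params(noise_sd_g = 0, gyro_noise_sd_dps = 0, step_frequency_cv = 0,
               amplitude_jitter = 0, ...)
}

# small two-group TUG-only cohort measure table, memoised per test file run
make_tug_measures <- function(pA, pB, n_per_group, seed) {
  recs <- simulate_cohort(list(list(params = pA, n = n_per_group),
                               list(params = pB, n = n_per_group)),
                          seed = seed, tasks = "TUG")
  suppressWarnings(extract_cohort(recs))
}

# total TUG durations per participant x trial straight from recording
# lengths (contiguous segmentation makes these equal to total_duration)
cohort_duration_matrix <- function(params, n, seed) {
  recs <- simulate_cohort(list(list(params = params, n = n)), seed = seed,
                          tasks = "TUG")
  man <- attr(recs, "manifest")
  dur <- vapply(recs, function(r) length(r$acc_v) / r$fs, numeric(1))
  matrix(dur, ncol = 2, byrow = TRUE,
         dimnames = list(unique(man$participant_id), c("t1", "t2")))
}
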