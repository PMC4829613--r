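# Shared fixtures, built in code and memoized for the session. The study
# cohort uses the default design (34 individuals, 10 pulses per level,
# 12-15 energy levels) at 250 Hz; RMS-based statistics are insensitive to
# the sampling rate.

.fixtures <- new.env(parent = emptyenv())

studyConfig <- function(seed = 1, ...) {
  cohortConfig(sampling_rate = 250, seed = seed, ...)
}

# full-design cohort plus its normalized feature table
studyCohort <- function() {
  if (is.null(.fixtures$study)) {
    cohort <- simulateCohort(studyConfig())
    records <- normalizeFeatures(buildFeatureTable(cohort))
    .fixtures$study <- list(cohort = cohort, records = records)
  }
  .fixtures$study
}

# cheap cohort for unit-level checks
smallCohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- studyConfig(seed = 5, n_individuals = 6, pulses_per_level = 3)
    cohort <- simulateCohort(cfg)
    records <- normalizeFeatures(buildFeatureTable(cohort))
    .fixtures$small <- list(config = cfg, cohort = cohort, records = records)
  }
  .fixtures$small
}

# a deterministic individual with all noise terms zeroed, for closed-form
# checks of the evoked-amplitude rule
noiselessProfile <- function(scale = 1.3, evoked_slope = 6) {
  data.frame(individual_id = "Z01", scale = scale, noise_sd = 0,
             sensitivity = 2, max_energy = 4.5, evoked_base = 8,
             evoked_slope = evoked_slope, trial_noise_sd = 0)
}

# minimal feature table from explicit columns
featureRecords <- function(id, rating, rms_p, rms_s = 1, trial_index = NULL) {
  n <- max(length(id), length(rating), length(rms_p), length(rms_s))
  data.frame(individual_id = rep_len(id, n),
             trial_index = if (is.null(trial_index)) seq_len(n) else trial_index,
             energy_J = rep_len(2, n),
             rating = rep_len(rating, n),
             rms_s = rep_len(rms_s, n),
             rms_p = rep_len(rms_p, n))
}
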