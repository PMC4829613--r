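test_that("profile sampling honors the design and the seed", {
  cfg <- studyConfig(seed = 7)
  prof <- sampleIndividualProfiles(cfg)
  expect_equal(nrow(prof), 34L)
  expect_true(all(prof$scale > 0))
  expect_true(all(prof$max_energy >= 3.75 & prof$max_energy <= 4.5))
  # sensitivity is calibrated so the top energy elicits a rating of ~8
  expect_equal(prof$sensitivity * prof$max_energy, rep(8, 34))

  expect_identical(prof, sampleIndividualProfiles(cfg))

  flat <- sampleIndividualProfiles(studyConfig(seed = 7, scale_spread = 0))
  expect_equal(flat$scale, rep(1, 34))
})

test_that("invalid configuration fields are reported by name", {
  expect_error(cohortConfig(n_individuals = 1), "n_individuals")
  expect_error(cohortConfig(pulses_per_level = 0), "pulses_per_level")
  expect_error(cohortConfig(sampling_rate = 333, epoch_halfwidth = 0.5),
               "whole number of samples")
  expect_error(cohortConfig(max_energy_range = c(4.5, 3.75)),
               "max_energy_range")
})

test_that("the evoked-amplitude rule is flat below the break and linear above", {
  cfg <- studyConfig()
  p <- noiselessProfile(scale = 1.3, evoked_slope = 6)
  tr <- lapply(c(2, 4, 5, 6), function(r)
    simulateTrial(p, 2, cfg, rating = r))
  # below the break the amplitude does not depend on the rating
  expect_identical(tr[[1]]$post, tr[[2]]$post)
  # one rating step above the break adds exactly scale * evoked_slope
  # times the unit waveform
  w <- evokedWaveform(cfg@sampling_rate, cfg@epoch_halfwidth)
  diff65 <- tr[[4]]$post - tr[[3]]$post
  expect_equal(diff65, 1.3 * 6 * w, tolerance = 1e-12)
  # with all noise off the segment is exactly amplitude * waveform
  amp6 <- 1.3 * (8 + 6 * (6 - 4))
  expect_equal(tr[[4]]$post, amp6 * w, tolerance = 1e-12)
  expect_equal(tr[[1]]$pre, numeric(length(w)))
})

test_that("trials have the configured segment length and energy bounds hold", {
  cfg1k <- cohortConfig(seed = 3)
  prof <- sampleIndividualProfiles(cfg1k)[1, ]
  tr <- simulateTrial(prof, 2, cfg1k)
  expect_length(tr$pre, 500L)
  expect_length(tr$post, 500L)
  expect_true(tr$rating %in% 0:10)
  expect_error(simulateTrial(prof, 0.5, cfg1k), "outside")
  expect_error(simulateTrial(prof, 5, cfg1k), "outside")
})

test_that("cohort simulation is seed-reproducible and follows the energy ladder", {
  cfg <- studyConfig(seed = 9, n_individuals = 2, pulses_per_level = 2)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(preSignals(a), preSignals(b))
  expect_identical(postSignals(a), postSignals(b))
  expect_identical(trialData(a), trialData(b))

  # forcing the calibrated maximum pins the number of levels and trials
  hi <- simulateCohort(studyConfig(seed = 2, n_individuals = 2,
                                   max_energy_range = c(4.5, 4.5)))
  expect_equal(as.vector(table(trialData(hi)$individual_id)), c(150L, 150L))
  expect_equal(length(unique(trialData(hi)$energy_J)), 15L)
  lo <- simulateCohort(studyConfig(seed = 2, n_individuals = 2,
                                   max_energy_range = c(3.75, 3.75)))
  expect_equal(as.vector(table(trialData(lo)$individual_id)), c(120L, 120L))
  expect_equal(length(unique(trialData(lo)$energy_J)), 12L)

  one <- simulateCohort(studyConfig(seed = 2, n_individuals = 2,
                                    pulses_per_level = 1,
                                    max_energy_range = c(4, 4)))
  expect_equal(as.vector(table(trialData(one)$individual_id)), c(13L, 13L))
})

test_that("with trial noise off, post-segment RMS is flat below and increasing above the break", {
  cfg <- studyConfig()
  p <- noiselessProfile()
  rms <- vapply(0:10, function(r)
    computeRMS(simulateTrial(p, 2, cfg, rating = r)$post), numeric(1))
  expect_equal(rms[1:5], rep(rms[1], 5))          # ratings 0..4 identical
  expect_true(all(diff(rms[5:11]) > 0))           # strictly increasing above 4
})
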