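## Synthetic laser-EEG cohort generator.
##
## The generative model stands in for the individual-specific factors
## (cortical anatomy, electrode impedance) that scale an individual's EEG:
## one log-normal scale factor per individual multiplies BOTH the
## spontaneous noise SD and the evoked amplitude, which is what induces the
## cross-individual correlation between spontaneous and evoked magnitudes
## and what z-score normalization is designed to cancel. The rating-response
## rule is flat below the pinprick threshold (NRS 4) and linear above it.

# cache of noise-variance gains of the zero-phase band-pass, keyed by
# (rate, low, high, order); gain = energy of the effective impulse response
.gain_cache <- new.env(parent = emptyenv())

.bandNoiseGain <- function(sampling_rate, low = 1, high = 30, order = 4) {
  key <- paste(sampling_rate, low, high, order, sep = "|")
  g <- .gain_cache[[key]]
  if (is.null(g)) {
    pad <- as.integer(round(4 * sampling_rate))
    imp <- c(numeric(pad), 1, numeric(pad))
    h <- bandpassFilter(imp, sampling_rate, low, high, order)
    g <- sum(h^2)
    .gain_cache[[key]] <- g
  }
  g
}

# band-limited (low-high Hz) Gaussian noise with stationary SD 'sd'; white
# noise is filtered with the same zero-phase band-pass used in
# preprocessing, with 2 s of padding on each side discarded so the kept
# samples are free of edge transients, then rescaled by the filter's noise
# gain so the process SD equals the target
.bandNoise <- function(n, sampling_rate, sd, low = 1, high = 30, order = 4) {
  if (sd <= 0) return(numeric(n))
  pad <- as.integer(round(2 * sampling_rate))
  w <- stats::rnorm(n + 2L * pad)
  y <- bandpassFilter(w, sampling_rate, low, high, order)
  y[(pad + 1L):(pad + n)] * (sd / sqrt(.bandNoiseGain(sampling_rate, low, high, order)))
}

#' Canonical evoked waveform
#'
#' The unit-amplitude laser-evoked waveform used by the simulator: a
#' biphasic shape with a negative (N2-like) lobe peaking 200 ms and a
#' positive (P2-like) lobe peaking 350 ms after stimulus onset, both
#' Gaussian-windowed and confined to the post-stimulus segment. The negative
#' peak has magnitude 1, so the simulator's amplitude parameter is the N2
#' peak amplitude in microvolts.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param halfwidth post-stimulus segment duration in seconds.
#' @return Numeric vector of \code{sampling_rate * halfwidth} samples.
#' @examples
#' w <- evokedWaveform(250)
#' computeRMS(w)  # waveform RMS, needed to map fitted slopes back to amplitudes
#' @export
evokedWaveform <- function(sampling_rate, halfwidth = 0.5) {
  K <- as.integer(round(sampling_rate * halfwidth))
  t <- (seq_len(K) - 1L) / sampling_rate
  -exp(-0.5 * ((t - 0.20) / 0.03)^2) + 0.8 * exp(-0.5 * ((t - 0.35) / 0.05)^2)
}

#' Draw per-individual latent profiles
#'
#' Samples one profile per individual from the population model in the
#' configuration: a log-normal scale factor (median 1, log-SD
#' \code{scale_spread}) shared by spontaneous and evoked magnitudes, a
#' maximum tolerated laser energy drawn uniformly on
#' \code{max_energy_range} (the simulator's stand-in for the per-individual
#' energy calibration), a rating sensitivity fixed so the expected rating at
#' maximum energy equals \code{target_rating}, and an evoked slope with
#' log-normal inter-individual jitter.
#'
#' @param config a [CohortConfig-class].
#' @param seed integer seed, or NULL to draw from the current RNG stream
#'   (used internally by [simulateCohort()]); defaults to the config seed.
#' @return data.frame with one row per individual and columns
#'   \code{individual_id}, \code{scale}, \code{noise_sd},
#'   \code{sensitivity}, \code{max_energy}, \code{evoked_base},
#'   \code{evoked_slope}, \code{trial_noise_sd}.
#' @export
sampleIndividualProfiles <- function(config, seed = config@seed) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config@n_individuals
  max_energy <- stats::runif(n, config@max_energy_range[1],
                             config@max_energy_range[2])
  data.frame(
    individual_id = sprintf("S%02d", seq_len(n)),
    scale = exp(stats::rnorm(n, 0, config@scale_spread)),
    noise_sd = rep(config@noise_sd, n),
    sensitivity = config@target_rating / max_energy,
    max_energy = max_energy,
    evoked_base = rep(config@evoked_base, n),
    evoked_slope = config@evoked_slope * exp(stats::rnorm(n, 0, config@slope_spread)),
    trial_noise_sd = rep(config@trial_noise_sd, n))
}

#' Simulate one laser-evoked trial
#'
#' Draws a single trial for one individual at one stimulus energy. The
#' rating is the latent response \code{sensitivity * energy} plus Gaussian
#' noise, rounded half-up and clipped to the 0--10 NRS range. The
#' pre-stimulus segment is band-limited (1--30 Hz) Gaussian noise with SD
#' \code{scale * noise_sd}; the post-stimulus segment is independent such
#' noise plus the evoked waveform with amplitude
#' \code{scale * (evoked_base + evoked_slope * max(0, rating - break))}
#' plus trial jitter, floored at zero.
#'
#' @param profile one row of [sampleIndividualProfiles()] output (as a
#'   data.frame or list).
#' @param energy stimulus energy in J; must lie between
#'   \code{config@energy_min} and \code{profile$max_energy}.
#' @param config a [CohortConfig-class].
#' @param rating optional forced NRS rating (integer 0--10), bypassing the
#'   latent rating draw; used in tests of the amplitude rule.
#' @return list with elements \code{pre}, \code{post} (numeric segment
#'   vectors), \code{rating} (integer) and \code{energy}.
#' @export
simulateTrial <- function(profile, energy, config, rating = NULL) {
  profile <- as.list(profile)
  if (energy < config@energy_min - 1e-9 || energy > profile$max_energy + 1e-9)
    stop(sprintf("energy %g J outside [%g, %g] J for individual %s",
                 energy, config@energy_min, profile$max_energy,
                 profile$individual_id))
  if (is.null(rating)) {
    latent <- profile$sensitivity * energy +
      stats::rnorm(1, 0, config@rating_noise_sd)
    rating <- .clip(roundHalfUp(latent), 0, 10)
  } else {
    stopifnot(rating >= 0, rating <= 10, rating == round(rating))
  }
  K <- .segmentLength(config)
  fs <- config@sampling_rate
  sd_eeg <- profile$scale * profile$noise_sd
  pre <- .bandNoise(K, fs, sd_eeg)
  post <- .bandNoise(K, fs, sd_eeg)
  amp <- profile$scale *
    (profile$evoked_base +
       profile$evoked_slope * max(0, rating - config@break_point)) +
    stats::rnorm(1, 0, profile$trial_noise_sd)
  amp <- max(0, amp)
  post <- post + amp * evokedWaveform(fs, config@epoch_halfwidth)
  list(pre = pre, post = post, rating = as.integer(rating), energy = energy)
}

#' Simulate a full cohort
#'
#' Generates, for every individual, \code{pulses_per_level} trials at each
#' energy from \code{energy_min} up to that individual's maximum in
#' \code{energy_step} increments (12--15 levels under the defaults, hence
#' 120--150 trials), in randomized order. All randomness is governed by
#' \code{config@seed}: the same configuration and seed reproduce the cohort
#' bit-identically.
#'
#' @param config a [CohortConfig-class].
#' @return An [EpochedTrialSet-class] with the ground-truth profiles and the
#'   configuration attached to its metadata.
#' @examples
#' cfg <- cohortConfig(n_individuals = 3, pulses_per_level = 2,
#'                     sampling_rate = 250, seed = 11)
#' cohort <- simulateCohort(cfg)
#' cohort
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  prof <- sampleIndividualProfiles(config, seed = NULL)
  K <- .segmentLength(config)
  pre_list <- post_list <- info_list <- vector("list", nrow(prof))
  for (j in seq_len(nrow(prof))) {
    p <- prof[j, ]
    n_levels <- floor((p$max_energy - config@energy_min) /
                        config@energy_step + 1e-9) + 1
    energies <- config@energy_min + config@energy_step * (seq_len(n_levels) - 1)
    schedule <- sample(rep(energies, each = config@pulses_per_level))
    pre_m <- post_m <- matrix(0, nrow = K, ncol = length(schedule))
    ratings <- integer(length(schedule))
    for (i in seq_along(schedule)) {
      tr <- simulateTrial(p, schedule[i], config)
      pre_m[, i] <- tr$pre
      post_m[, i] <- tr$post
      ratings[i] <- tr$rating
    }
    pre_list[[j]] <- pre_m
    post_list[[j]] <- post_m
    info_list[[j]] <- data.frame(
      individual_id = p$individual_id,
      trial_index = seq_along(schedule),
      energy_J = schedule,
      rating = ratings)
  }
  EpochedTrialSet(
    pre = do.call(cbind, pre_list),
    post = do.call(cbind, post_list),
    info = do.call(rbind, info_list),
    sampling_rate = config@sampling_rate,
    profiles = prof,
    config = config)
}
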