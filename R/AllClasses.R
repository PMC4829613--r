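#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Cohort simulation configuration
#'
#' An S4 container for all parameters of the synthetic laser-EEG cohort:
#' the experimental design (number of individuals, energy ladder, pulses per
#' level, sampling), and the population-level parameters of the generative
#' model from which per-individual profiles are drawn.
#'
#' @slot n_individuals number of simulated individuals.
#' @slot energy_min lowest laser energy (J).
#' @slot energy_step spacing of the energy ladder (J).
#' @slot pulses_per_level laser pulses delivered at each energy level.
#' @slot sampling_rate sampling rate of the simulated EEG (Hz).
#' @slot epoch_halfwidth half-width of the peri-stimulus epoch (s); pre- and
#'   post-stimulus segments each span this duration.
#' @slot break_point NRS rating separating low- from high-pain trials.
#' @slot seed integer seed controlling all randomness of the simulation.
#' @slot scale_spread standard deviation (log scale) of the per-individual
#'   log-normal scale factor shared by spontaneous and evoked magnitudes;
#'   0 fixes every scale factor at 1 (disables scale sharing).
#' @slot noise_sd baseline spontaneous-EEG standard deviation (microvolts)
#'   before the individual scale factor is applied.
#' @slot rating_noise_sd SD of trial-to-trial noise on the latent rating
#'   (NRS units).
#' @slot evoked_base evoked peak amplitude (microvolts) at and below the
#'   break point.
#' @slot evoked_slope mean evoked amplitude increment (microvolts) per NRS
#'   unit above the break point.
#' @slot slope_spread log-scale SD of per-individual jitter on evoked_slope.
#' @slot trial_noise_sd SD of additive trial-to-trial evoked-amplitude
#'   jitter (microvolts).
#' @slot max_energy_range range (J) from which each individual's maximum
#'   tolerated energy is drawn uniformly.
#' @slot target_rating expected rating at an individual's maximum energy;
#'   fixes the latent rating sensitivity.
#'
#' @seealso [cohortConfig()] for the user-facing constructor.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    n_individuals = "integer",
    energy_min = "numeric",
    energy_step = "numeric",
    pulses_per_level = "integer",
    sampling_rate = "numeric",
    epoch_halfwidth = "numeric",
    break_point = "numeric",
    seed = "integer",
    scale_spread = "numeric",
    noise_sd = "numeric",
    rating_noise_sd = "numeric",
    evoked_base = "numeric",
    evoked_slope = "numeric",
    slope_spread = "numeric",
    trial_noise_sd = "numeric",
    max_energy_range = "numeric",
    target_rating = "numeric"
  ),
  prototype(
    n_individuals = 34L,
    energy_min = 1.0,
    energy_step = 0.25,
    pulses_per_level = 10L,
    sampling_rate = 1000,
    epoch_halfwidth = 0.5,
    break_point = 4,
    seed = 1L,
    scale_spread = 0.4,
    noise_sd = 10,
    rating_noise_sd = 0.8,
    evoked_base = 8,
    evoked_slope = 6,
    slope_spread = 0.1,
    trial_noise_sd = 2,
    max_energy_range = c(3.75, 4.5),
    target_rating = 8
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  chk <- function(cond, field, what) {
    if (!cond) msgs <<- c(msgs, sprintf("invalid '%s': %s", field, what))
  }
  chk(length(object@n_individuals) == 1L && object@n_individuals >= 2L,
      "n_individuals", "must be a single integer >= 2")
  chk(length(object@pulses_per_level) == 1L && object@pulses_per_level >= 1L,
      "pulses_per_level", "must be a single integer >= 1")
  chk(object@energy_min > 0, "energy_min", "must be positive")
  chk(object@energy_step > 0, "energy_step", "must be positive")
  chk(object@sampling_rate > 0, "sampling_rate", "must be positive")
  chk(object@epoch_halfwidth > 0, "epoch_halfwidth", "must be positive")
  nsamp <- object@sampling_rate * object@epoch_halfwidth
  chk(isTRUE(all.equal(nsamp, round(nsamp))), "sampling_rate",
      "sampling_rate * epoch_halfwidth must be a whole number of samples")
  chk(object@scale_spread >= 0, "scale_spread", "must be >= 0")
  chk(object@noise_sd > 0, "noise_sd", "must be positive")
  chk(object@rating_noise_sd >= 0, "rating_noise_sd", "must be >= 0")
  chk(object@evoked_base >= 0, "evoked_base", "must be >= 0")
  chk(object@evoked_slope >= 0, "evoked_slope", "must be >= 0")
  chk(object@trial_noise_sd >= 0, "trial_noise_sd", "must be >= 0")
  chk(length(object@max_energy_range) == 2L &&
        object@max_energy_range[1] <= object@max_energy_range[2] &&
        object@max_energy_range[1] > object@energy_min,
      "max_energy_range",
      "must be an increasing pair above energy_min")
  chk(object@break_point >= 0 && object@break_point <= 10,
      "break_point", "must lie in [0, 10]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a cohort configuration
#'
#' Defaults mirror the study design the simulator emulates: 34 individuals,
#' laser energies from 1 J in 0.25 J steps up to a per-individual maximum in
#' 3.75--4.5 J (12--15 levels), 10 pulses per level (120--150 trials), EEG
#' sampled at 1000 Hz, epochs of 0.5 s on either side of the stimulus, and a
#' low/high-pain break point at NRS = 4.
#'
#' @param n_individuals number of individuals in the cohort.
#' @param energy_min,energy_step,pulses_per_level energy ladder design.
#' @param sampling_rate,epoch_halfwidth signal sampling (Hz) and epoch
#'   half-width (s); their product must be a whole number of samples.
#'   Statistics downstream operate on RMS magnitudes and are insensitive to
#'   the sampling rate, so 250 Hz is a convenient faster choice.
#' @param break_point NRS rating separating low-pain (<= break) from
#'   high-pain (> break) trials.
#' @param seed integer seed for the simulation.
#' @param scale_spread,noise_sd,rating_noise_sd,evoked_base,evoked_slope,slope_spread,trial_noise_sd,max_energy_range,target_rating
#'   population parameters of the generative model; see
#'   [CohortConfig-class].
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(n_individuals = 4, sampling_rate = 250, seed = 7)
#' cfg
#' @export
cohortConfig <- function(n_individuals = 34,
                         energy_min = 1.0,
                         energy_step = 0.25,
                         pulses_per_level = 10,
                         sampling_rate = 1000,
                         epoch_halfwidth = 0.5,
                         break_point = 4,
                         seed = 1,
                         scale_spread = 0.4,
                         noise_sd = 10,
                         rating_noise_sd = 0.8,
                         evoked_base = 8,
                         evoked_slope = 6,
                         slope_spread = 0.1,
                         trial_noise_sd = 2,
                         max_energy_range = c(3.75, 4.5),
                         target_rating = 8) {
  new("CohortConfig",
      n_individuals = as.integer(n_individuals),
      energy_min = as.numeric(energy_min),
      energy_step = as.numeric(energy_step),
      pulses_per_level = as.integer(pulses_per_level),
      sampling_rate = as.numeric(sampling_rate),
      epoch_halfwidth = as.numeric(epoch_halfwidth),
      break_point = as.numeric(break_point),
      seed = as.integer(seed),
      scale_spread = as.numeric(scale_spread),
      noise_sd = as.numeric(noise_sd),
      rating_noise_sd = as.numeric(rating_noise_sd),
      evoked_base = as.numeric(evoked_base),
      evoked_slope = as.numeric(evoked_slope),
      slope_spread = as.numeric(slope_spread),
      trial_noise_sd = as.numeric(trial_noise_sd),
      max_energy_range = as.numeric(max_energy_range),
      target_rating = as.numeric(target_rating))
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat(sprintf("  individuals: %d, pulses/level: %d, energies: from %g J in %g J steps\n",
              object@n_individuals, object@pulses_per_level,
              object@energy_min, object@energy_step))
  cat(sprintf("  max energy: U[%g, %g] J, target rating at max: %g\n",
              object@max_energy_range[1], object@max_energy_range[2],
              object@target_rating))
  cat(sprintf("  sampling: %g Hz, epoch: +/- %g s, break point: NRS %g, seed: %d\n",
              object@sampling_rate, object@epoch_halfwidth,
              object@break_point, object@seed))
  cat(sprintf("  scale spread (sdlog): %g, noise SD: %g uV, evoked base/slope: %g/%g uV\n",
              object@scale_spread, object@noise_sd,
              object@evoked_base, object@evoked_slope))
  invisible(NULL)
})

#' Epoched laser-EEG trial set
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one column
#' per stimulus trial and one row per time sample. Two assays are required:
#' \code{"pre"} (the spontaneous segment, -0.5 s to 0 s, stimulus sample
#' excluded) and \code{"post"} (the evoked segment, 0 s to +0.5 s, stimulus
#' sample included). Trial metadata live in \code{colData}: columns
#' \code{individual_id}, \code{trial_index}, \code{energy_J} and
#' \code{rating} (integer NRS 0--10). The sampling rate (Hz) and, for
#' simulated cohorts, the ground-truth individual profiles are stored in
#' \code{metadata()}.
#'
#' @seealso [simulateCohort()], [buildFeatureTable()], [trialData()],
#'   [profiles()], [samplingRate()]
#' @exportClass EpochedTrialSet
setClass("EpochedTrialSet", contains = "SummarizedExperiment")

setValidity("EpochedTrialSet", function(object) {
  msgs <- character()
  an <- assayNames(object)
  if (!all(c("pre", "post") %in% an))
    msgs <- c(msgs, "assays must include 'pre' and 'post'")
  else if (!identical(dim(assay(object, "pre")), dim(assay(object, "post"))))
    msgs <- c(msgs, "'pre' and 'post' assays must have identical dimensions")
  need <- c("individual_id", "trial_index", "energy_J", "rating")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msgs <- c(msgs, sprintf("colData lacks column(s): %s",
                            paste(miss, collapse = ", ")))
  if ("rating" %in% colnames(colData(object))) {
    r <- colData(object)$rating
    if (length(r) && (any(r < 0 | r > 10) || any(r != round(r))))
      msgs <- c(msgs, "ratings must be integers in [0, 10]")
  }
  sr <- metadata(object)$sampling_rate
  if (is.null(sr) || !is.numeric(sr) || length(sr) != 1L || sr <= 0)
    msgs <- c(msgs, "metadata()$sampling_rate must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' Assemble an EpochedTrialSet from segment matrices and trial metadata
#'
#' @param pre,post numeric matrices, one column per trial and one row per
#'   time sample; \code{pre} spans [-0.5 s, 0) and \code{post} [0, 0.5 s).
#' @param info data.frame with one row per trial and columns
#'   \code{individual_id}, \code{trial_index}, \code{energy_J},
#'   \code{rating}.
#' @param sampling_rate sampling rate in Hz.
#' @param profiles optional data.frame of ground-truth individual profiles
#'   (see [sampleIndividualProfiles()]).
#' @param config optional [CohortConfig-class] recording how the set was
#'   simulated.
#' @return An [EpochedTrialSet-class].
#' @export
EpochedTrialSet <- function(pre, post, info, sampling_rate,
                            profiles = NULL, config = NULL) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  info <- as.data.frame(info)
  stopifnot(ncol(pre) == nrow(info))
  meta <- list(sampling_rate = as.numeric(sampling_rate))
  if (!is.null(profiles)) meta$profiles <- profiles
  if (!is.null(config)) meta$config <- config
  if (nrow(info) > 0L)
    colnames(pre) <- colnames(post) <-
      paste0(info$individual_id, ".", info$trial_index)
  se <- SummarizedExperiment(
    assays = list(pre = pre, post = post),
    colData = DataFrame(info, row.names = colnames(pre)),
    metadata = meta)
  new("EpochedTrialSet", se)
}

setMethod("show", "EpochedTrialSet", function(object) {
  ids <- unique(colData(object)$individual_id)
  cat(sprintf("EpochedTrialSet: %d trials, %d individuals, %d samples/segment @ %g Hz\n",
              ncol(object), length(ids), nrow(object),
              metadata(object)$sampling_rate))
  r <- colData(object)$rating
  if (length(r))
    cat(sprintf("  ratings: %d-%d (median %g); energies: %g-%g J\n",
                min(r), max(r), stats::median(r),
                min(colData(object)$energy_J), max(colData(object)$energy_J)))
  if (!is.null(metadata(object)$profiles))
    cat("  ground-truth individual profiles attached\n")
  invisible(NULL)
})
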