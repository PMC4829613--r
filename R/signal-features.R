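#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, the standard
#' event-related-potential preprocessing step. The default band, 1--30 Hz,
#' retains the N2/P2 laser-evoked components while suppressing drift and
#' line noise. An order-4 filter is applied in each direction, so the
#' effective magnitude response is the squared Butterworth response:
#' passband gain within a few percent at mid-band and more than 20 dB
#' attenuation one octave outside the band.
#'
#' @param x numeric vector of signal samples (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy 0 < low < high <
#'   sampling_rate / 2.
#' @param order Butterworth order per pass.
#' @return Filtered vector of the same length as \code{x}.
#' @examples
#' fs <- 250
#' t <- seq(0, 4, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t) + 0.5  # in-band tone plus DC offset
#' y <- bandpassFilter(x, fs)
#' @export
bandpassFilter <- function(x, sampling_rate, low = 1, high = 30, order = 4) {
  if (!is.numeric(x) || length(x) == 0L)
    stop("'x' must be a non-empty numeric vector")
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf(
      "band edges must satisfy 0 < low < high < %g Hz (Nyquist); got [%g, %g]",
      nyq, low, high))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Extract a baseline-corrected peri-stimulus epoch
#'
#' Cuts a [-halfwidth, +halfwidth) window around a stimulus sample out of a
#' continuous record and subtracts the mean of the pre-stimulus segment from
#' the whole epoch. The convention is half-open: the stimulus sample itself
#' starts the post-stimulus segment.
#'
#' @param x continuous signal vector.
#' @param event_index 1-based sample index of the stimulus onset.
#' @param sampling_rate sampling rate in Hz.
#' @param halfwidth epoch half-width in seconds (default 0.5 s).
#' @return A list with elements \code{pre} and \code{post} (each of
#'   \code{sampling_rate * halfwidth} samples, baseline-corrected), or
#'   \code{NULL} with a warning when the window does not fit in the record
#'   (the trial is dropped).
#' @export
epochAndBaseline <- function(x, event_index, sampling_rate, halfwidth = 0.5) {
  K <- sampling_rate * halfwidth
  if (!isTRUE(all.equal(K, round(K))))
    stop("sampling_rate * halfwidth must be a whole number of samples")
  K <- as.integer(round(K))
  if (event_index - K < 1L || event_index + K - 1L > length(x)) {
    warning(sprintf(
      "epoch at sample %d exceeds the record (length %d); trial dropped",
      event_index, length(x)))
    return(NULL)
  }
  pre <- x[(event_index - K):(event_index - 1L)]
  post <- x[event_index:(event_index + K - 1L)]
  bl <- mean(pre)
  list(pre = pre - bl, post = post - bl)
}

#' Root-mean-square magnitude of a segment
#'
#' The single-trial magnitude measure: \code{sqrt(mean(x^2))} over the K
#' samples of a segment. Applied to the pre-stimulus segment it yields the
#' spontaneous magnitude RMS_S, to the post-stimulus segment the evoked
#' magnitude RMS_P.
#'
#' @param x non-empty numeric vector of samples.
#' @return The RMS (same units as \code{x}).
#' @examples
#' computeRMS(c(3, -4))  # sqrt(12.5)
#' @export
computeRMS <- function(x) {
  if (!is.numeric(x) || length(x) == 0L)
    stop("cannot compute the RMS of an empty segment")
  sqrt(mean(x^2))
}

#' Reduce an epoched trial set to its feature table
#'
#' Computes per-trial RMS_S (spontaneous, pre-stimulus segment) and RMS_P
#' (evoked, post-stimulus segment), optionally after baseline-correcting
#' each epoch by its pre-stimulus mean. The result is the row unit of every
#' downstream analysis; the normalized feature nRMS_P is absent until
#' [normalizeFeatures()] adds it.
#'
#' @param trials an [EpochedTrialSet-class].
#' @param baseline_correct subtract each epoch's pre-stimulus mean from both
#'   segments before computing RMS (default TRUE, mirroring conventional
#'   preprocessing).
#' @return data.frame with columns \code{individual_id},
#'   \code{trial_index}, \code{energy_J}, \code{rating}, \code{rms_s},
#'   \code{rms_p}; one row per trial, in trial order.
#' @export
buildFeatureTable <- function(trials, baseline_correct = TRUE) {
  stopifnot(is(trials, "EpochedTrialSet"))
  info <- trialData(trials)
  key <- paste(info$individual_id, info$trial_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual_id, trial_index) pairs in the trial set")
  pre <- preSignals(trials)
  post <- postSignals(trials)
  if (ncol(pre) == 0L) {
    return(data.frame(individual_id = character(), trial_index = integer(),
                      energy_J = numeric(), rating = integer(),
                      rms_s = numeric(), rms_p = numeric()))
  }
  if (baseline_correct) {
    bl <- colMeans(pre)
    pre <- sweep(pre, 2L, bl)
    post <- sweep(post, 2L, bl)
  }
  data.frame(
    individual_id = info$individual_id,
    trial_index = info$trial_index,
    energy_J = info$energy_J,
    rating = info$rating,
    rms_s = sqrt(colMeans(pre^2)),
    rms_p = sqrt(colMeans(post^2)),
    row.names = NULL)
}
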