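#' Fit an individual's spontaneous-magnitude baseline
#'
#' Estimates the mean and sample SD (divisor n - 1) of one individual's
#' spontaneous magnitudes RMS_S over all of that individual's trials. This
#' baseline defines the reference distribution against which the
#' individual's evoked magnitudes are expressed as z-scores. Only
#' pre-stimulus data enter the baseline, so it is available even when no
#' reliable pain rating can be obtained from the individual.
#'
#' @param records feature-table rows (see [buildFeatureTable()]) of a single
#'   individual; at least 2 rows with non-constant \code{rms_s}.
#' @return list with \code{individual_id}, \code{mu_s}, \code{sigma_s},
#'   \code{n_trials}.
#' @export
fitBaseline <- function(records) {
  id <- unique(records$individual_id)
  if (length(id) != 1L)
    stop("'records' must belong to exactly one individual")
  x <- records$rms_s
  if (length(x) < 2L)
    stop(sprintf("individual %s: need >= 2 trials to fit a baseline", id))
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0)
    stop(sprintf("individual %s: degenerate baseline (zero spontaneous variance)", id))
  list(individual_id = id, mu_s = mean(x), sigma_s = sigma,
       n_trials = length(x))
}

#' Normalize one individual's evoked magnitudes against a baseline
#'
#' @param records feature rows of one individual.
#' @param baseline a baseline from [fitBaseline()] for the same individual.
#' @param mode \code{"zscore"} (default): \code{(rms_p - mu_s) / sigma_s};
#'   \code{"divide_mean"}: \code{rms_p / mu_s}; \code{"subtract_mean"}:
#'   \code{rms_p - mu_s}.
#' @return \code{records} with an \code{nrms_p} column.
#' @export
applyBaseline <- function(records, baseline,
                          mode = c("zscore", "divide_mean", "subtract_mean")) {
  mode <- match.arg(mode)
  if (!all(records$individual_id == baseline$individual_id))
    stop("baseline individual does not match the records' individual")
  records$nrms_p <- switch(mode,
    zscore = (records$rms_p - baseline$mu_s) / baseline$sigma_s,
    divide_mean = records$rms_p / baseline$mu_s,
    subtract_mean = records$rms_p - baseline$mu_s)
  records
}

#' Normalize a feature table by each individual's spontaneous distribution
#'
#' For every individual, fits the spontaneous baseline over all of that
#' individual's trials and expresses each trial's evoked magnitude relative
#' to it. The default z-score mode makes the normalized feature invariant to
#' any common positive rescaling of an individual's signals, which is the
#' mechanism by which individual-specific scale factors (anatomy, electrode
#' impedance) are removed before cross-individual analysis.
#'
#' @param records a feature table from [buildFeatureTable()].
#' @param mode normalization mode; see [applyBaseline()].
#' @return The table with an added \code{nrms_p} column (row order
#'   preserved).
#' @export
normalizeFeatures <- function(records,
                              mode = c("zscore", "divide_mean", "subtract_mean")) {
  mode <- match.arg(mode)
  out <- lapply(split(records, records$individual_id), function(r) {
    applyBaseline(r, fitBaseline(r), mode)
  })
  res <- do.call(rbind, out)
  res[order(match(paste(res$individual_id, res$trial_index),
                  paste(records$individual_id, records$trial_index))), ,
      drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Kolmogorov-Smirnov normality diagnostic
#'
#' One-sample KS test of a standardized magnitude sample against the
#' standard normal, the diagnostic used to justify treating an individual's
#' spontaneous magnitudes as a Gaussian reference population. Parameters are
#' estimated from the sample itself before the comparison, which is known to
#' inflate p-values (the Lilliefors effect); the result is reported as a
#' descriptive diagnostic and no trial is excluded on its outcome.
#'
#' @param x numeric vector of at least 8 magnitudes.
#' @return list with \code{statistic} (KS D) and \code{p_value}.
#' @export
checkNormality <- function(x) {
  if (length(x) < 8L)
    stop("need at least 8 values for the normality diagnostic")
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate (constant) sample")
  kt <- suppressWarnings(stats::ks.test((x - mean(x)) / s, "pnorm"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
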