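#' Per-level one-way ANOVA across individuals
#'
#' Within each unit pain-level bin, a one-way fixed-effects ANOVA of the
#' chosen magnitude feature with individual as the factor, over all trials
#' falling in the bin. The F statistic measures between-individual relative
#' to within-individual variability at that pain level; effective
#' normalization should lower it. Bins with fewer than 2 individuals
#' holding at least \code{min_trials} trials are skipped with a notice.
#'
#' @param records a feature table (normalized if \code{feature =
#'   "nrms_p"}).
#' @param feature \code{"rms_p"} or \code{"nrms_p"}.
#' @param bins bin definitions; defaults to the unit bins only.
#' @param min_trials minimum trials per individual within a bin.
#' @return data.frame with columns \code{bin}, \code{f_stat},
#'   \code{df_between}, \code{df_within}, \code{p_value},
#'   \code{n_individuals}, \code{n_trials}.
#' @export
anovaFByLevel <- function(records, feature = c("rms_p", "nrms_p"),
                          bins = painLevelBins(aggregates = FALSE),
                          min_trials = 2) {
  feature <- match.arg(feature)
  long <- binByPainLevel(records, bins)
  rows <- list()
  for (b in bins$label) {
    g <- long[long$bin == b, , drop = FALSE]
    keep <- names(which(table(g$individual_id) >= min_trials))
    g <- g[g$individual_id %in% keep, , drop = FALSE]
    if (length(keep) < 2L) {
      message(sprintf("bin %s: fewer than 2 individuals with >= %d trials; skipped",
                      b, min_trials))
      next
    }
    fit <- stats::lm(g[[feature]] ~ factor(g$individual_id))
    av <- stats::anova(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, f_stat = av$`F value`[1],
      df_between = av$Df[1], df_within = av$Df[2],
      p_value = av$`Pr(>F)`[1],
      n_individuals = length(keep), n_trials = nrow(g))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Optimal single-cut low/high-pain threshold for one individual
#'
#' Exhaustive search for the cut on a magnitude feature that best separates
#' the individual's low-pain (rating <= break) from high-pain (rating >
#' break) trials under the rule "feature above threshold implies high
#' pain". Candidates are the midpoints between consecutive distinct sorted
#' feature values plus one cut below the minimum and one above the maximum;
#' accuracy ties break toward the smallest threshold so the result is
#' deterministic.
#'
#' @param records feature rows of a single individual containing both
#'   classes.
#' @param feature \code{"rms_p"} or \code{"nrms_p"}.
#' @param break_point NRS break (default 4).
#' @return list with \code{individual_id}, \code{threshold},
#'   \code{accuracy}.
#' @export
optimalBinaryThreshold <- function(records, feature = c("rms_p", "nrms_p"),
                                   break_point = 4) {
  feature <- match.arg(feature)
  id <- unique(records$individual_id)
  if (length(id) != 1L)
    stop("'records' must belong to exactly one individual")
  x <- records[[feature]]
  is_high <- records$rating > break_point
  if (!any(is_high) || all(is_high))
    stop(sprintf("individual %s: one pain class absent; excluded", id))
  v <- sort(unique(x))
  cands <- c(v[1] - 1,
             if (length(v) > 1L) (v[-length(v)] + v[-1]) / 2,
             v[length(v)] + 1)
  acc <- vapply(cands, function(thr) mean((x > thr) == is_high), numeric(1))
  best <- which(acc == max(acc))[1]  # smallest threshold among ties
  list(individual_id = id, threshold = cands[best], accuracy = acc[best])
}

#' Per-individual linear fit on high-pain trials
#'
#' OLS of the magnitude feature on the rating, restricted to one
#' individual's high-pain (rating > break) trials — the individual-specific
#' prediction model whose slope and intercept variances quantify
#' inter-individual variability. Requires at least 3 high-pain trials
#' spanning 2 distinct ratings.
#'
#' @param records feature rows of a single individual.
#' @param feature \code{"rms_p"} or \code{"nrms_p"}.
#' @param break_point NRS break (default 4).
#' @return list with \code{individual_id}, \code{slope}, \code{intercept},
#'   \code{mse}, \code{n}.
#' @export
individualHighpainFit <- function(records, feature = c("rms_p", "nrms_p"),
                                  break_point = 4) {
  feature <- match.arg(feature)
  id <- unique(records$individual_id)
  if (length(id) != 1L)
    stop("'records' must belong to exactly one individual")
  h <- records[records$rating > break_point, , drop = FALSE]
  if (nrow(h) < 3L || length(unique(h$rating)) < 2L)
    stop(sprintf("individual %s: insufficient high-pain trials for a fit", id))
  f <- .olsFit(h$rating, h[[feature]])
  list(individual_id = id, slope = f$slope, intercept = f$intercept,
       mse = f$sse / f$n, n = f$n)
}

#' Cross-individual variance comparison of a model parameter
#'
#' Sample variances of a per-individual parameter (threshold, slope or
#' intercept) computed from raw versus normalized features, with the
#' variance-ratio F-test (F = larger / smaller variance, numerator degrees
#' of freedom matching the larger-variance sample; two-sided p obtained by
#' doubling the one-tailed tail probability, capped at 1). A shrinking
#' variance after normalization indicates reduced inter-individual
#' variability in that parameter.
#'
#' @param values_raw,values_norm per-individual parameter values under the
#'   raw and the normalized feature (>= 3 each).
#' @param parameter_name label for the comparison.
#' @return list with \code{parameter_name}, \code{var_raw},
#'   \code{var_norm}, \code{f_stat}, \code{df1}, \code{df2},
#'   \code{p_value} (NA when either variance is zero),
#'   \code{degenerate}.
#' @export
compareVariances <- function(values_raw, values_norm,
                             parameter_name = "parameter") {
  if (length(values_raw) < 3L || length(values_norm) < 3L)
    stop("need at least 3 individuals in each set")
  v1 <- stats::var(values_raw)
  v2 <- stats::var(values_norm)
  out <- list(parameter_name = parameter_name, var_raw = v1, var_norm = v2)
  if (v1 <= 0 || v2 <= 0) {
    out$f_stat <- NA_real_; out$df1 <- NA_integer_; out$df2 <- NA_integer_
    out$p_value <- NA_real_; out$degenerate <- TRUE
    return(out)
  }
  if (v1 >= v2) {
    f <- v1 / v2; df1 <- length(values_raw) - 1L; df2 <- length(values_norm) - 1L
  } else {
    f <- v2 / v1; df1 <- length(values_norm) - 1L; df2 <- length(values_raw) - 1L
  }
  out$f_stat <- f; out$df1 <- df1; out$df2 <- df2
  out$p_value <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  out$degenerate <- FALSE
  out
}

#' Inter-individual parameter variability before and after normalization
#'
#' Convenience wrapper computing, for every individual able to support
#' them, the optimal binary threshold and the high-pain regression slope
#' and intercept under both the raw and the normalized feature, then
#' comparing the cross-individual variances of each parameter. The raw and
#' normalized parameters live on different scales (microvolts versus
#' z-units), so the coefficient of variation of each parameter set is also
#' reported as a scale-free diagnostic (an extension beyond the plain
#' variance comparison).
#'
#' @param records a normalized feature table (with \code{nrms_p}).
#' @param break_point NRS break (default 4).
#' @return list with \code{parameters} (data.frame of per-individual
#'   threshold/slope/intercept for both features) and \code{comparison}
#'   (data.frame with variances, F, p and CVs per parameter).
#' @export
parameterVariability <- function(records, break_point = 4) {
  if (is.null(records$nrms_p))
    stop("records must contain 'nrms_p'; run normalizeFeatures() first")
  per <- lapply(split(records, records$individual_id), function(r) {
    res <- try({
      thr_r <- optimalBinaryThreshold(r, "rms_p", break_point)
      thr_n <- optimalBinaryThreshold(r, "nrms_p", break_point)
      fit_r <- individualHighpainFit(r, "rms_p", break_point)
      fit_n <- individualHighpainFit(r, "nrms_p", break_point)
      data.frame(individual_id = r$individual_id[1],
                 threshold_raw = thr_r$threshold, threshold_norm = thr_n$threshold,
                 slope_raw = fit_r$slope, slope_norm = fit_n$slope,
                 intercept_raw = fit_r$intercept, intercept_norm = fit_n$intercept)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      message(sprintf("individual %s excluded: %s", r$individual_id[1],
                      attr(res, "condition")$message))
      return(NULL)
    }
    res
  })
  pars <- do.call(rbind, per)
  rownames(pars) <- NULL
  cmp <- lapply(c("threshold", "slope", "intercept"), function(p) {
    raw <- pars[[paste0(p, "_raw")]]
    nrm <- pars[[paste0(p, "_norm")]]
    vc <- compareVariances(raw, nrm, p)
    data.frame(parameter = p, var_raw = vc$var_raw, var_norm = vc$var_norm,
               f_stat = vc$f_stat, p_value = vc$p_value,
               cv_raw = stats::sd(raw) / abs(mean(raw)),
               cv_norm = stats::sd(nrm) / abs(mean(nrm)))
  })
  list(parameters = pars, comparison = do.call(rbind, cmp))
}
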