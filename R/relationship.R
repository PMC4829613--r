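#' Default pain-level bins
#'
#' Unit NRS bins (0,1], (1,2], ..., (7,8], a combined top bin (8,10] (the
#' highest ratings are too rare in some individuals to stand alone), and the
#' two aggregate bins (0,4] (low pain) and (4,10] (high pain). Bins are
#' half-open (lower, upper], so a rating of 4 falls in (3,4] and in the
#' low-pain aggregate, and rating-0 trials fall in no bin.
#'
#' @param aggregates include the (0,4] and (4,10] aggregate bins.
#' @return data.frame with columns \code{label}, \code{lower},
#'   \code{upper}, \code{aggregate}.
#' @export
painLevelBins <- function(aggregates = TRUE) {
  lower <- c(0:7, 8)
  upper <- c(1:8, 10)
  b <- data.frame(label = sprintf("(%d,%d]", lower, upper),
                  lower = lower, upper = upper, aggregate = FALSE)
  if (aggregates) {
    b <- rbind(data.frame(label = c("(0,4]", "(4,10]"),
                          lower = c(0, 4), upper = c(4, 10),
                          aggregate = TRUE), b)
  }
  b
}

#' Assign feature records to pain-level bins
#'
#' Each record is assigned to every bin whose half-open interval
#' (lower, upper] contains its rating; unit bins are disjoint but the
#' aggregate bins overlap them, so records may be duplicated across bins in
#' the long-format result.
#'
#' @param records a feature table.
#' @param bins a bin definition as from [painLevelBins()].
#' @return The records in long format with an added \code{bin} column
#'   (one copy per containing bin).
#' @export
binByPainLevel <- function(records, bins = painLevelBins()) {
  if (any(bins$lower >= bins$upper))
    stop("malformed bin: 'lower' must be strictly below 'upper'")
  if (any(records$rating < 0 | records$rating > 10))
    stop("ratings must lie in [0, 10]")
  pieces <- lapply(seq_len(nrow(bins)), function(i) {
    inb <- records$rating > bins$lower[i] & records$rating <= bins$upper[i]
    if (!any(inb)) return(NULL)
    cbind(bin = bins$label[i], records[inb, , drop = FALSE])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Per-individual magnitude summaries within each pain-level bin
#'
#' For every bin and individual with at least \code{min_trials} trials in
#' that bin, the mean and SD of RMS_S and RMS_P across those trials; the
#' inputs to the cross-individual correlation analysis.
#'
#' @param records a feature table.
#' @param bins bin definitions.
#' @param min_trials minimum trials per individual per bin (default 2, so
#'   the SD is defined).
#' @return data.frame with columns \code{bin}, \code{individual_id},
#'   \code{mean_rms_s}, \code{sd_rms_s}, \code{mean_rms_p}, \code{sd_rms_p},
#'   \code{n_trials}.
#' @export
levelSummaries <- function(records, bins = painLevelBins(), min_trials = 2) {
  long <- binByPainLevel(records, bins)
  grp <- split(long, list(long$bin, long$individual_id), drop = TRUE)
  rows <- lapply(grp, function(g) {
    if (nrow(g) < min_trials) return(NULL)
    data.frame(bin = g$bin[1], individual_id = g$individual_id[1],
               mean_rms_s = mean(g$rms_s), sd_rms_s = stats::sd(g$rms_s),
               mean_rms_p = mean(g$rms_p), sd_rms_p = stats::sd(g$rms_p),
               n_trials = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-individual correlation of spontaneous and evoked magnitudes
#'
#' Within each pain-level bin, the Pearson correlation across individuals
#' between per-individual mean RMS_S and mean RMS_P, and likewise between
#' the SDs. A positive correlation indicates that individuals with larger
#' spontaneous magnitudes also produce larger evoked magnitudes — the
#' empirical basis for using the spontaneous distribution as a
#' normalization reference. Bins represented by fewer than 3 individuals
#' are skipped with a notice.
#'
#' @param summaries output of [levelSummaries()].
#' @return data.frame with one row per bin and statistic
#'   (\code{statistic} is \code{"mean"} or \code{"sd"}): columns \code{bin},
#'   \code{statistic}, \code{r}, \code{p_value}, \code{n}.
#' @export
correlateLevelSummaries <- function(summaries) {
  rows <- list()
  for (b in unique(summaries$bin)) {
    s <- summaries[summaries$bin == b, , drop = FALSE]
    if (nrow(s) < 3L) {
      message(sprintf("bin %s: only %d individual(s); skipped", b, nrow(s)))
      next
    }
    for (stat in c("mean", "sd")) {
      xs <- s[[paste0(stat, "_rms_s")]]
      yp <- s[[paste0(stat, "_rms_p")]]
      ct <- stats::cor.test(xs, yp, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, statistic = stat, r = unname(ct$estimate),
        p_value = ct$p.value, n = nrow(s))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.olsFit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       sse = sum(res^2), n = length(y))
}

#' Global linear fit of response on rating
#'
#' Ordinary least squares of a response magnitude on the NRS rating over
#' the full rating range; the single-line alternative against which the
#' two-piecewise model is compared. MSE is the descriptive SSE/n.
#'
#' @param rating,response paired numeric vectors (>= 3 points spanning at
#'   least 2 distinct ratings).
#' @return list with \code{slope}, \code{intercept}, \code{mse}, \code{n}.
#' @export
fitGlobalLinear <- function(rating, response) {
  stopifnot(length(rating) == length(response))
  if (length(rating) < 3L)
    stop("need at least 3 points for a global linear fit")
  if (length(unique(rating)) < 2L)
    stop("degenerate fit: all ratings identical")
  f <- .olsFit(rating, response)
  list(slope = f$slope, intercept = f$intercept, mse = f$sse / f$n, n = f$n)
}

# one segment of the piecewise model: OLS when >= 2 distinct ratings,
# otherwise the segment mean (slope 0); NULL segment when empty
.segmentFit <- function(rating, response) {
  if (length(rating) == 0L) return(NULL)
  if (length(unique(rating)) >= 2L) {
    f <- .olsFit(rating, response)
    list(slope = f$slope, intercept = f$intercept, sse = f$sse, n = f$n)
  } else {
    m <- mean(response)
    list(slope = 0, intercept = m, sse = sum((response - m)^2),
         n = length(response))
  }
}

#' Two-piecewise linear fit with a fixed break point
#'
#' Fits independent OLS lines to the low segment (rating <= break point)
#' and the high segment (rating > break point) with no continuity
#' constraint, and pools the error as total SSE over total n. Because the
#' single global line is a member of the piecewise family, the pooled MSE
#' can never exceed the global-fit MSE on the same data.
#'
#' @param rating,response paired numeric vectors.
#' @param break_point NRS break separating the segments (default 4, the
#'   pinprick-pain threshold).
#' @return list with \code{low} and \code{high} segment fits (each
#'   \code{slope}, \code{intercept}, \code{sse}, \code{n}, or NULL when the
#'   segment is empty), \code{break_point}, \code{mse}, \code{n}.
#' @export
fitPiecewiseLinear <- function(rating, response, break_point = 4) {
  stopifnot(length(rating) == length(response))
  lo <- rating <= break_point
  low <- .segmentFit(rating[lo], response[lo])
  high <- .segmentFit(rating[!lo], response[!lo])
  if (is.null(low) && is.null(high))
    stop("both segments empty: no data to fit")
  sse <- sum(c(low$sse, high$sse))
  n <- sum(c(low$n, high$n))
  list(low = low, high = high, break_point = break_point,
       mse = sse / n, n = n)
}

#' Fit both rating-response models for every individual
#'
#' For each individual, the response magnitudes are first averaged across
#' trials within each observed rating level (the per-level means carry the
#' rating-response shape; raw-trial fitting is available via
#' \code{per_level = FALSE}), then both the global linear and the
#' two-piecewise model are fitted to the (rating, mean response) points.
#' Individuals whose points cannot support a global fit (fewer than 3
#' points or a single distinct rating) are skipped with a notice.
#'
#' @param records a feature table.
#' @param feature \code{"rms_p"} or \code{"nrms_p"}.
#' @param break_point NRS break for the piecewise model.
#' @param per_level average trials within each rating level before fitting
#'   (default TRUE).
#' @return data.frame with one row per individual: \code{individual_id},
#'   \code{mse_global}, \code{mse_piecewise}, \code{slope_global},
#'   \code{slope_low}, \code{slope_high}, \code{n_points}.
#' @export
fitIndividualModels <- function(records, feature = c("rms_p", "nrms_p"),
                                break_point = 4, per_level = TRUE) {
  feature <- match.arg(feature)
  rows <- lapply(split(records, records$individual_id), function(r) {
    if (per_level) {
      y <- tapply(r[[feature]], r$rating, mean)
      x <- as.numeric(names(y))
      y <- as.numeric(y)
    } else {
      x <- r$rating
      y <- r[[feature]]
    }
    if (length(x) < 3L || length(unique(x)) < 2L) {
      message(sprintf("individual %s: too few rating levels; skipped",
                      r$individual_id[1]))
      return(NULL)
    }
    g <- fitGlobalLinear(x, y)
    pw <- fitPiecewiseLinear(x, y, break_point)
    data.frame(individual_id = r$individual_id[1],
               mse_global = g$mse, mse_piecewise = pw$mse,
               slope_global = g$slope,
               slope_low = if (is.null(pw$low)) NA_real_ else pw$low$slope,
               slope_high = if (is.null(pw$high)) NA_real_ else pw$high$slope,
               n_points = g$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of global versus piecewise fit error
#'
#' Two-sided paired t-test on per-individual MSE differences
#' (global - piecewise), with the per-model mean and SD. When every
#' difference is exactly zero the comparison is degenerate and is reported
#' as t = 0, p = 1 with a flag.
#'
#' @param fits output of [fitIndividualModels()] (>= 3 individuals).
#' @return list with \code{mean_global}, \code{sd_global},
#'   \code{mean_piecewise}, \code{sd_piecewise}, \code{t}, \code{df},
#'   \code{p_value}, \code{degenerate}.
#' @export
compareFitModels <- function(fits) {
  if (nrow(fits) < 3L)
    stop("need at least 3 individuals for a paired model comparison")
  d <- fits$mse_global - fits$mse_piecewise
  out <- list(mean_global = mean(fits$mse_global),
              sd_global = stats::sd(fits$mse_global),
              mean_piecewise = mean(fits$mse_piecewise),
              sd_piecewise = stats::sd(fits$mse_piecewise),
              df = length(d) - 1L)
  if (all(d == 0)) {
    out$t <- 0; out$p_value <- 1; out$degenerate <- TRUE
  } else {
    tt <- stats::t.test(fits$mse_global, fits$mse_piecewise, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$p_value <- tt$p.value
    out$degenerate <- FALSE
  }
  out
}
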