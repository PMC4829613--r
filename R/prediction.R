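#' Leave-one-individual-out partitions
#'
#' One partition per individual, in sorted id order: the individual is held
#' out in full and every other individual forms the training set. No trial
#' of the held-out individual — and in particular no rating — ever enters
#' training.
#'
#' @param individual_ids vector of unique individual ids (>= 2).
#' @return list of partitions, each a list with \code{held_out} and
#'   \code{training_ids}.
#' @export
loioPartitions <- function(individual_ids) {
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  ids <- sort(as.character(individual_ids))
  if (length(ids) < 2L)
    stop("leave-one-individual-out needs at least 2 individuals")
  lapply(ids, function(id)
    list(held_out = id, training_ids = setdiff(ids, id)))
}

#' One-dimensional linear discriminant classifier
#'
#' Gaussian equal-variance LDA on a single magnitude feature: class means
#' and the pooled within-class variance are estimated from training trials,
#' and a trial is assigned to the class with the larger linear discriminant
#' score. Priors default to the empirical class frequencies; with equal
#' priors the decision boundary reduces to the midpoint of the two class
#' means.
#'
#' @param x numeric feature values of the training trials.
#' @param is_high logical, TRUE for high-pain (rating > 4) trials.
#' @param priors \code{"empirical"} (training class frequencies) or
#'   \code{"equal"}.
#' @return An object of class \code{lda1d}: list with class means, pooled
#'   SD, priors and the decision boundary.
#' @export
trainLda1d <- function(x, is_high, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  stopifnot(length(x) == length(is_high))
  n_low <- sum(!is_high); n_high <- sum(is_high)
  if (n_low < 2L || n_high < 2L)
    stop("both classes need at least 2 training trials")
  m_low <- mean(x[!is_high]); m_high <- mean(x[is_high])
  s2 <- (sum((x[!is_high] - m_low)^2) + sum((x[is_high] - m_high)^2)) /
    (length(x) - 2L)
  if (s2 <= 0)
    stop("zero pooled within-class variance; classifier undefined")
  p <- if (priors == "equal") c(low = 0.5, high = 0.5) else
    c(low = n_low, high = n_high) / length(x)
  # equal discriminant scores at:
  boundary <- (m_low + m_high) / 2 + s2 * log(p["low"] / p["high"]) / (m_high - m_low)
  structure(list(m_low = m_low, m_high = m_high, s2 = s2, priors = p,
                 boundary = unname(boundary)),
            class = "lda1d")
}

#' Predict low/high-pain classes from a 1-D LDA classifier
#'
#' @param object an \code{lda1d} classifier.
#' @param newdata numeric feature values.
#' @param ... unused.
#' @return logical vector, TRUE where high pain is predicted (the larger
#'   discriminant score; ties go to high).
#' @export
predict.lda1d <- function(object, newdata, ...) {
  d_low <- newdata * object$m_low / object$s2 -
    object$m_low^2 / (2 * object$s2) + log(object$priors["low"])
  d_high <- newdata * object$m_high / object$s2 -
    object$m_high^2 / (2 * object$s2) + log(object$priors["high"])
  unname(d_high >= d_low)
}

#' Two-stage pain prediction for one held-out individual
#'
#' Stage 1 classifies every held-out trial as low or high pain with a 1-D
#' LDA trained on the other individuals. Stage 2 fits OLS
#' \code{rating = alpha * feature + c} on the training individuals' true
#' high-pain trials and predicts ratings for (a) held-out trials predicted
#' high and (b) held-out trials truly high; both sets are scored by mean
#' absolute error against the reported ratings, with predictions clipped to
#' the 0--10 NRS range. Normalized features must have been computed per
#' individual from spontaneous data only (as [normalizeFeatures()] does),
#' so the held-out individual contributes no rating information.
#'
#' @param partition one partition from [loioPartitions()].
#' @param records a feature table covering all individuals.
#' @param feature \code{"rms_p"} or \code{"nrms_p"}.
#' @param priors LDA priors, \code{"empirical"} or \code{"equal"}.
#' @param break_point NRS break (default 4).
#' @return list with \code{individual_id}, \code{trials} (per-trial
#'   data.frame: rating, predicted_class, predicted_rating),
#'   \code{accuracy}, \code{mae_predicted_high} (NA with a flag when no
#'   trial is predicted high), \code{mae_real_high}, \code{n_trials}.
#' @export
twoStagePredict <- function(partition, records, feature = c("rms_p", "nrms_p"),
                            priors = c("empirical", "equal"), break_point = 4) {
  feature <- match.arg(feature)
  priors <- match.arg(priors)
  train <- records[records$individual_id %in% partition$training_ids, , drop = FALSE]
  test <- records[records$individual_id == partition$held_out, , drop = FALSE]
  if (nrow(test) == 0L)
    stop(sprintf("no trials for held-out individual %s", partition$held_out))
  clf <- trainLda1d(train[[feature]], train$rating > break_point, priors)
  train_high <- train[train$rating > break_point, , drop = FALSE]
  if (nrow(train_high) < 3L)
    stop("need at least 3 high-pain training trials for stage 2")
  reg <- .olsFit(train_high[[feature]], train_high$rating)

  pred_high <- predict(clf, test[[feature]])
  pred_rating <- .clip(reg$intercept + reg$slope * test[[feature]], 0, 10)
  true_high <- test$rating > break_point

  mae <- function(sel) if (any(sel))
    mean(abs(test$rating[sel] - pred_rating[sel])) else NA_real_
  list(
    individual_id = partition$held_out,
    trials = data.frame(
      trial_index = test$trial_index,
      rating = test$rating,
      predicted_class = ifelse(pred_high, "high", "low"),
      predicted_rating = ifelse(pred_high, pred_rating, NA_real_)),
    accuracy = mean(pred_high == true_high),
    mae_predicted_high = mae(pred_high),
    mae_real_high = mae(true_high),
    no_predicted_high = !any(pred_high),
    n_trials = nrow(test))
}

#' Run the two-stage predictor over all leave-one-individual-out folds
#'
#' @param records a feature table (normalized when \code{feature =
#'   "nrms_p"}).
#' @param feature,priors,break_point passed to [twoStagePredict()].
#' @return data.frame with one row per held-out individual:
#'   \code{individual_id}, \code{accuracy}, \code{mae_predicted_high},
#'   \code{mae_real_high}, \code{n_trials}.
#' @export
runTwoStage <- function(records, feature = c("rms_p", "nrms_p"),
                        priors = c("empirical", "equal"), break_point = 4) {
  feature <- match.arg(feature)
  priors <- match.arg(priors)
  parts <- loioPartitions(unique(records$individual_id))
  rows <- lapply(parts, function(p) {
    o <- twoStagePredict(p, records, feature, priors, break_point)
    data.frame(individual_id = o$individual_id, accuracy = o$accuracy,
               mae_predicted_high = o$mae_predicted_high,
               mae_real_high = o$mae_real_high, n_trials = o$n_trials)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare prediction performance under raw and normalized features
#'
#' Per-metric mean and SD across individuals, and two-sided paired t-tests
#' of raw versus normalized outcomes (accuracy and both MAEs). Individuals
#' with an undefined MAE in either arm are dropped from that metric's
#' pairing.
#'
#' @param outcomes_raw,outcomes_norm outputs of [runTwoStage()] for the
#'   same individuals under the raw and normalized feature.
#' @return data.frame with one row per metric: means, SDs, t, p_value and
#'   the number of paired individuals.
#' @export
evaluateAndCompare <- function(outcomes_raw, outcomes_norm) {
  if (!identical(sort(outcomes_raw$individual_id),
                 sort(outcomes_norm$individual_id)))
    stop("outcome sets cover different individuals")
  a <- outcomes_raw[order(outcomes_raw$individual_id), ]
  b <- outcomes_norm[order(outcomes_norm$individual_id), ]
  metric <- function(name) {
    x <- a[[name]]; y <- b[[name]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    d <- x - y
    res <- data.frame(
      metric = name,
      mean_raw = mean(x), sd_raw = stats::sd(x),
      mean_norm = mean(y), sd_norm = stats::sd(y),
      t = NA_real_, p_value = NA_real_, n = length(x))
    if (length(d) >= 3L && any(d != 0)) {
      tt <- stats::t.test(x, y, paired = TRUE)
      res$t <- unname(tt$statistic); res$p_value <- tt$p.value
    } else if (all(d == 0)) {
      res$t <- 0; res$p_value <- 1
    }
    res
  }
  out <- rbind(metric("accuracy"), metric("mae_predicted_high"),
               metric("mae_real_high"))
  rownames(out) <- NULL
  out
}
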