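test_that("leave-one-individual-out partitions cover each individual once", {
  ids <- sprintf("S%02d", 1:34)
  parts <- loioPartitions(ids)
  expect_length(parts, 34L)
  expect_setequal(vapply(parts, `[[`, "", "held_out"), ids)
  for (p in parts) {
    expect_false(p$held_out %in% p$training_ids)
    expect_length(p$training_ids, 33L)
  }
  two <- loioPartitions(c("a", "b"))
  expect_equal(two[[1]]$training_ids, "b")
  expect_equal(two[[2]]$training_ids, "a")
  expect_error(loioPartitions(c("a", "a")), "unique")
  expect_error(loioPartitions("a"), "at least 2")
})

test_that("1-D LDA has the closed-form midpoint boundary under equal priors", {
  clf <- trainLda1d(c(0, 1, 3, 4), c(FALSE, FALSE, TRUE, TRUE), "equal")
  expect_equal(clf$boundary, 2, tolerance = 1e-12)
  expect_equal(predict(clf, c(1.9, 2.1)), c(FALSE, TRUE))

  # decision direction flips when the class magnitudes swap
  rev <- trainLda1d(c(3, 4, 0, 1), c(FALSE, FALSE, TRUE, TRUE), "equal")
  expect_equal(predict(rev, c(0.5, 3.5)), c(TRUE, FALSE))

  expect_error(trainLda1d(c(1, 2, 3), c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(trainLda1d(c(1, 1, 2, 2), c(FALSE, FALSE, TRUE, TRUE) &
                            c(TRUE, TRUE, FALSE, FALSE)), "both classes")
})

test_that("LDA decisions match the Gaussian discriminant oracle and MASS::lda", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    is_high <- c(FALSE, FALSE, TRUE, TRUE, runif(n) > 0.5)
    x <- rnorm(n + 4, mean = ifelse(is_high, 2, 0), sd = 1)
    clf <- trainLda1d(x, is_high)
    xt <- rnorm(15, 1, 2)
    # oracle: class-conditional Gaussians with pooled variance and priors
    d_low <- dnorm(xt, clf$m_low, sqrt(clf$s2)) * clf$priors["low"]
    d_high <- dnorm(xt, clf$m_high, sqrt(clf$s2)) * clf$priors["high"]
    expect_equal(predict(clf, xt), unname(d_high >= d_low))
  }
  skip_if_not_installed("MASS")
  is_high <- rep(c(FALSE, TRUE), each = 25)
  x <- rnorm(50, ifelse(is_high, 2, 0))
  clf <- trainLda1d(x, is_high)
  m <- MASS::lda(data.frame(x = x), grouping = is_high)
  xt <- seq(-2, 4, by = 0.1)
  expect_equal(predict(clf, xt),
               as.logical(predict(m, data.frame(x = xt))$class))
})

test_that("LDA boundary converges to the class-mean midpoint at large n", {
  set.seed(52)
  n <- 10000
  x <- c(rnorm(n, 0), rnorm(n, 3))
  clf <- trainLda1d(x, rep(c(FALSE, TRUE), each = n), "equal")
  expect_equal(clf$boundary, 1.5, tolerance = 0.02 * 1.5)
})

test_that("no information leaks from the held-out individual", {
  sm <- smallCohort()
  rec <- sm$records
  parts <- loioPartitions(unique(rec$individual_id))
  p <- parts[[3]]
  base <- twoStagePredict(p, rec, "nrms_p")
  # scrambling the held-out individual's ratings must leave every
  # prediction bit-identical (only the scored accuracy/MAE may change)
  rec2 <- rec
  held <- rec2$individual_id == p$held_out
  set.seed(53)
  rec2$rating[held] <- sample(rec2$rating[held])
  alt <- twoStagePredict(p, rec2, "nrms_p")
  expect_identical(base$trials$predicted_class, alt$trials$predicted_class)
  expect_identical(base$trials$predicted_rating, alt$trials$predicted_rating)
})

test_that("stage-2 regression reproduces the closed-form OLS solution", {
  sm <- smallCohort()
  rec <- sm$records
  p <- loioPartitions(unique(rec$individual_id))[[1]]
  out <- twoStagePredict(p, rec, "rms_p")
  train <- rec[rec$individual_id != p$held_out & rec$rating > 4, ]
  x <- train$rms_p; y <- train$rating
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  test <- rec[rec$individual_id == p$held_out, ]
  manual <- pmin(10, pmax(0, ic + sl * test$rms_p))
  pred_high <- out$trials$predicted_class == "high"
  expect_equal(out$trials$predicted_rating[pred_high], manual[pred_high],
               tolerance = 1e-9)
})

test_that("perfect features yield perfect two-stage predictions", {
  # feature numerically equal to the rating: stage 1 separable, stage 2 exact
  rec <- do.call(rbind, lapply(c("A", "B", "C"), function(id)
    featureRecords(id, rating = rep(1:8, 2), rms_p = rep(1:8, 2))))
  out <- runTwoStage(rec, "rms_p", priors = "equal")
  expect_equal(out$accuracy, rep(1, 3))
  expect_equal(out$mae_real_high, rep(0, 3), tolerance = 1e-9)
  expect_equal(out$mae_predicted_high, rep(0, 3), tolerance = 1e-9)
})

test_that("per-individual scale jitter hurts raw features but not z-scored ones", {
  rec <- studyCohort()$records[, c("individual_id", "trial_index", "energy_J",
                                   "rating", "rms_s", "rms_p")]
  set.seed(54)
  jit <- setNames(exp(rnorm(length(unique(rec$individual_id)), 0, 0.8)),
                  unique(rec$individual_id))
  rec2 <- rec
  rec2$rms_s <- rec$rms_s * jit[rec$individual_id]
  rec2$rms_p <- rec$rms_p * jit[rec$individual_id]
  n1 <- normalizeFeatures(rec)
  n2 <- normalizeFeatures(rec2)
  expect_equal(n2$nrms_p, n1$nrms_p, tolerance = 1e-9)
  raw1 <- runTwoStage(n1, "rms_p")
  raw2 <- runTwoStage(n2, "rms_p")
  expect_gt(mean(raw2$mae_real_high), mean(raw1$mae_real_high))
  norm1 <- runTwoStage(n1, "nrms_p")
  norm2 <- runTwoStage(n2, "nrms_p")
  expect_equal(norm2$mae_real_high, norm1$mae_real_high, tolerance = 1e-9)
})

test_that("outcome comparison computes the paired t statistic by hand", {
  mk <- function(acc, mae) data.frame(
    individual_id = c("A", "B", "C"), accuracy = acc,
    mae_predicted_high = mae, mae_real_high = mae, n_trials = 10)
  a <- mk(c(0.7, 0.8, 0.9), c(2, 3, 4))
  b <- mk(c(0.7, 0.8, 0.9), c(1, 1, 1))   # MAE differences 1, 2, 3
  cmp <- evaluateAndCompare(a, b)
  expect_equal(cmp$t[cmp$metric == "mae_real_high"], 2 * sqrt(3),
               tolerance = 1e-9)
  same <- evaluateAndCompare(a, a)
  expect_equal(same$p_value, rep(1, 3))
  expect_equal(same$mean_raw, same$mean_norm)
  expect_error(evaluateAndCompare(a, mk(1, 1)[1, ]), "different individuals")
})
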