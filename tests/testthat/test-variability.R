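# records with all trials at rating 5 so everything lands in one unit bin
binRecords <- function(values_by_id) {
  do.call(rbind, lapply(names(values_by_id), function(id)
    featureRecords(id, rating = 5, rms_p = values_by_id[[id]])))
}

test_that("per-level ANOVA matches hand-computed sums of squares", {
  same <- anovaFByLevel(binRecords(list(A = c(1, 2, 3), B = c(1, 2, 3))))
  expect_equal(same$f_stat, 0)

  sep <- anovaFByLevel(binRecords(list(A = c(1, 2, 3), B = c(4, 5, 6))))
  expect_equal(sep$f_stat, 13.5)
  expect_equal(sep$df_between, 1L)
  expect_equal(sep$df_within, 4L)

  # from-scratch sum-of-squares oracle on random groupings
  set.seed(41)
  for (i in 1:20) {
    vals <- lapply(setNames(1:4, LETTERS[1:4]),
                   function(j) rnorm(sample(3:8, 1), mean = j))
    res <- anovaFByLevel(binRecords(vals))
    x <- unlist(vals)
    g <- rep(names(vals), lengths(vals))
    gm <- tapply(x, g, mean)
    ssb <- sum(lengths(vals) * (gm[names(vals)] - mean(x))^2)
    ssw <- sum((x - gm[g])^2)
    f <- (ssb / (length(vals) - 1)) / (ssw / (length(x) - length(vals)))
    expect_equal(res$f_stat, unname(f), tolerance = 1e-9)
  }

  # a single qualifying individual is not enough
  expect_message(
    none <- anovaFByLevel(binRecords(list(A = c(1, 2, 3), B = 2))),
    "skipped")
  expect_null(none)
})

test_that("the exhaustive threshold search returns the documented optima", {
  r1 <- optimalBinaryThreshold(
    featureRecords("A", rating = c(2, 2, 6, 6), rms_p = c(1, 2, 3, 4)))
  expect_equal(r1$threshold, 2.5)
  expect_equal(r1$accuracy, 1)

  # tied optima resolve to the smallest threshold
  r2 <- optimalBinaryThreshold(
    featureRecords("A", rating = c(2, 2, 6, 6), rms_p = c(1, 3, 2, 4)))
  expect_equal(r2$accuracy, 0.75)
  expect_equal(r2$threshold, 1.5)

  # separable features are always classified perfectly
  set.seed(42)
  for (i in 1:20) {
    lo <- runif(5, 0, 1); hi <- runif(5, 2, 3)
    r <- optimalBinaryThreshold(
      featureRecords("A", rating = rep(c(2, 6), each = 5), rms_p = c(lo, hi)))
    expect_equal(r$accuracy, 1)
  }

  expect_error(
    optimalBinaryThreshold(featureRecords("A", rating = 2, rms_p = 1:3)),
    "class absent")
})

test_that("high-pain fits recover exact lines and flag unusable individuals", {
  ex <- individualHighpainFit(
    featureRecords("A", rating = c(5, 6, 7, 2), rms_p = c(10, 12, 14, 0)))
  expect_equal(ex$slope, 2)
  expect_equal(ex$intercept, 0)
  expect_equal(ex$mse, 0)
  expect_equal(ex$n, 3L)

  flat <- individualHighpainFit(
    featureRecords("A", rating = c(5, 6, 7), rms_p = c(3, 3, 3)))
  expect_equal(flat$slope, 0)

  expect_error(
    individualHighpainFit(featureRecords("A", rating = c(5, 5, 5), rms_p = 1:3)),
    "insufficient")
})

test_that("variance comparison computes the ratio test with matched df", {
  vc <- compareVariances(c(1, 2, 3), c(2, 4, 6))
  expect_equal(vc$var_raw, 1)
  expect_equal(vc$var_norm, 4)
  expect_equal(vc$f_stat, 4)
  expect_equal(vc$df1, 2L)   # numerator df follows the larger variance
  expect_equal(vc$p_value, min(1, 2 * pf(4, 2, 2, lower.tail = FALSE)))

  eq <- compareVariances(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$f_stat, 1)
  expect_equal(eq$p_value, 1)

  dg <- compareVariances(rep(1, 3), c(1, 2, 3))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p_value))
})
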