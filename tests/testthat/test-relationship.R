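test_that("bins are half-open (lower, upper] with overlapping aggregates", {
  bins <- painLevelBins()
  r4 <- binByPainLevel(featureRecords("A", rating = 4, rms_p = 1), bins)
  expect_setequal(r4$bin, c("(3,4]", "(0,4]"))
  r5 <- binByPainLevel(featureRecords("A", rating = 5, rms_p = 1), bins)
  expect_setequal(r5$bin, c("(4,5]", "(4,10]"))
  r0 <- binByPainLevel(featureRecords("A", rating = 0, rms_p = 1), bins)
  expect_null(r0)
  expect_error(
    binByPainLevel(featureRecords("A", 5, 1),
                   data.frame(label = "x", lower = 2, upper = 2)),
    "malformed bin")
})

test_that("cross-individual correlations recover exact proportionality", {
  mk <- function(ms, mp) data.frame(
    bin = "(4,10]", individual_id = c("A", "B", "C"),
    mean_rms_s = ms, sd_rms_s = ms / 2,
    mean_rms_p = mp, sd_rms_p = mp / 2, n_trials = 10)
  up <- correlateLevelSummaries(mk(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(up$r[up$statistic == "mean"], 1)
  dn <- correlateLevelSummaries(mk(c(1, 2, 3), c(6, 4, 2)))
  expect_equal(dn$r[dn$statistic == "mean"], -1)
  # fewer than 3 individuals: bin skipped with a notice
  expect_message(out <- correlateLevelSummaries(mk(1:3, 1:3)[1:2, ]),
                 "skipped")
  expect_null(out)
})

test_that("global linear fits match hand-solved normal equations", {
  f <- fitGlobalLinear(c(5, 6, 7), c(1, 2, 3))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, -4)
  expect_equal(f$mse, 0)

  g <- fitGlobalLinear(c(0, 1, 2), c(0, 1, 0))
  expect_equal(g$slope, 0)
  expect_equal(g$intercept, 1 / 3)
  expect_equal(g$mse, 2 / 9)

  expect_error(fitGlobalLinear(c(3, 3, 3), c(1, 2, 3)), "degenerate")
  expect_error(fitGlobalLinear(c(1, 2), c(1, 2)), "at least 3")
})

test_that("piecewise fit is exact on piecewise data and handles segment fallbacks", {
  r <- 1:8
  y <- ifelse(r <= 4, 1, r - 3)
  pw <- fitPiecewiseLinear(r, y)
  expect_equal(pw$mse, 0)
  expect_equal(pw$low$slope, 0)
  expect_equal(pw$high$slope, 1)
  expect_equal(pw$high$intercept, -3)

  # single-rating segment falls back to its mean with slope 0
  one <- fitPiecewiseLinear(c(3, 3, 5, 6, 7), c(2, 4, 1, 2, 3))
  expect_equal(one$low$slope, 0)
  expect_equal(one$low$intercept, 3)
  expect_error(fitPiecewiseLinear(numeric(0), numeric(0)), "empty")
})

test_that("piecewise never fits worse than global, and OLS matches the closed form", {
  set.seed(31)
  closed <- function(x, y) {   # two-parameter OLS, closed form
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    c(slope = sl, intercept = mean(y) - sl * mean(x))
  }
  for (i in 1:100) {
    x <- sample(0:10, sample(8:30, 1), replace = TRUE)
    if (length(unique(x)) < 2 || all(x <= 4) || all(x > 4)) next
    y <- rnorm(length(x), x, 2)
    g <- fitGlobalLinear(x, y)
    pw <- fitPiecewiseLinear(x, y)
    expect_lte(pw$mse, g$mse + 1e-12)
    cf <- closed(x, y)
    expect_equal(g$slope, unname(cf["slope"]), tolerance = 1e-9)
    expect_equal(g$intercept, unname(cf["intercept"]), tolerance = 1e-9)
  }
})

test_that("segment-wise least squares agrees with a brute-force minimizer", {
  set.seed(32)
  for (i in 1:10) {
    x <- sample(5:10, 20, replace = TRUE)
    y <- rnorm(20, x, 1)
    f <- fitPiecewiseLinear(x, y)$high
    sse <- function(p) sum((y - p[1] - p[2] * x)^2)
    opt <- optim(c(0, 0), sse, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(f$sse, opt$value, tolerance = 1e-6)
  }
})

test_that("paired model comparison reports the hand-computed t statistic", {
  fits <- data.frame(individual_id = c("A", "B", "C"),
                     mse_global = c(2, 3, 4), mse_piecewise = c(1, 1, 1))
  cmp <- compareFitModels(fits)   # differences 1, 2, 3
  expect_equal(cmp$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(cmp$df, 2L)
  expect_false(cmp$degenerate)

  same <- data.frame(individual_id = c("A", "B", "C"),
                     mse_global = 1:3, mse_piecewise = 1:3)
  cmp0 <- compareFitModels(same)
  expect_true(cmp0$degenerate)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_value, 1)
})
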