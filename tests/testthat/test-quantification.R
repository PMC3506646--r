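test_that("threshold Cq interpolates the FMM spline through the curve", {
  ## exact integer hit
  curve <- c(1, 2, 4, 8, 16, 32, 64, 128)
  expect_equal(cqValue(thresholdCq(curve, 8)), 4)
  ## exact doubling geometry: threshold 2^7 crossed at cycle 7
  curve <- 2^(1:12)
  expect_lt(abs(cqValue(thresholdCq(curve, 2^7)) - 7), 0.01)
  ## never crosses -> explicit missing marker
  r <- thresholdCq(c(1, 2, 3, 4, 5), 100)
  expect_true(is.na(cqValue(r)))
  expect_identical(r@flag, "no-crossing")
  ## threshold inside the baseline -> flagged
  r <- thresholdCq(c(50, 60, 70), 10)
  expect_identical(r@flag, "threshold-inside-baseline")
  expect_error(thresholdCq(c(1, NA, 3), 5), "finite")
})

test_that("5PLM round-trips its own parameters on noise-free data", {
  truth <- fivePLMParams(fb = 120, fmax = 3400, cInfl = 26.5,
                         bGrowth = 1.35, gAsym = 0.7)
  fit <- fit5plm(predict5plm(truth, 1:60))
  expect_equal(fit@fb, truth@fb, tolerance = 1e-4)
  expect_equal(fit@fmax, truth@fmax, tolerance = 1e-4)
  expect_equal(fit@cInfl, truth@cInfl, tolerance = 1e-4)
  expect_equal(fit@bGrowth, truth@bGrowth, tolerance = 1e-4)
  expect_equal(fit@gAsym, truth@gAsym, tolerance = 1e-4)
})

test_that("with unit asymmetry the 5PLM reduces to the 4-parameter logistic", {
  truth <- fivePLMParams(fb = 100, fmax = 3000, cInfl = 28, bGrowth = 1.5,
                         gAsym = 1)
  y <- predict5plm(truth, 1:60)
  fit5 <- fit5plm(y)
  ## independent 4PL fit of the same data
  df <- data.frame(x = 1:60, y = y)
  fit4 <- minpack.lm::nlsLM(y ~ fb + fmax / (1 + exp(-(x - cc) / b)),
                            data = df,
                            start = list(fb = 90, fmax = 2800, cc = 27,
                                         b = 1.3))
  cf <- coef(fit4)
  expect_equal(fit5@gAsym, 1, tolerance = 1e-3)
  expect_equal(fit5@cInfl, cf[["cc"]], tolerance = 1e-3)
  expect_equal(fit5@bGrowth, cf[["b"]], tolerance = 1e-3)
})

test_that("the SDM has its closed form and always precedes the inflection", {
  ## symmetric logistic: c - b log(2 + sqrt(3))
  p <- fivePLMParams(fb = 0, fmax = 3000, cInfl = 30, bGrowth = 1.5,
                     gAsym = 1)
  expect_equal(cqValue(sdmCq(p)), 30 - 1.5 * log(2 + sqrt(3)),
               tolerance = 1e-10)
  expect_lt(abs(cqValue(sdmCq(p)) - 28.02), 0.01)
  ## analytic position agrees with a fine-grid numeric maximiser
  set.seed(21)
  for (i in 1:12) {
    p <- fivePLMParams(fb = 50, fmax = 3500, cInfl = runif(1, 20, 32),
                       bGrowth = runif(1, 0.8, 2.5),
                       gAsym = exp(runif(1, log(0.3), log(4))))
    grid <- seq(1, 60, by = 1e-3)
    d2 <- diff(predict5plm(p, grid), differences = 2)
    numeric <- grid[which.max(d2) + 1]
    analytic <- cqValue(sdmCq(p))
    expect_lt(abs(analytic - numeric), 0.01)
    expect_lt(analytic, p@cInfl + p@bGrowth * log(p@gAsym))  # inflection
  }
})

test_that("repeat summaries have zero dispersion for identical curves and track known jitter", {
  tr <- quietRun(50000, 1.9)
  base <- ampFluorescence(tr)
  same <- matrix(rep(base, 10), ncol = 10)
  s <- repeatSummary(same, threshold = 100)
  expect_equal(s$sdCqThreshold, 0, tolerance = 1e-8)
  expect_equal(s$sdCqSdm, 0, tolerance = 1e-8)
  expect_equal(s$cvPlateau, 0, tolerance = 1e-12)
  ## fractional-cycle shifts by {0, 0.1, 0.2} appear in the threshold Cq sd
  p <- fit5plm(base)
  offs <- c(0, 0.1, 0.2)
  shifted <- vapply(offs, function(o) predict5plm(p, (1:60) - o),
                    numeric(60))
  s2 <- repeatSummary(shifted, threshold = 100)
  expect_lt(abs(s2$sdCqThreshold - sd(offs)) / sd(offs), 0.05)
})

test_that("the default threshold policy uses the lowest SDM height in the set", {
  tr <- quietRun(50000, 1.9)
  base <- ampFluorescence(tr)
  fits <- list(fit5plm(base), fit5plm(base * 1.15))
  thr <- sdmThreshold(fits)
  expect_equal(thr, min(vapply(fits, sdmFluorescence, 0)), tolerance = 1e-9)
  s <- repeatSummary(cbind(base, base * 1.15))
  expect_equal(s$threshold, thr, tolerance = 1e-6)
})

test_that("oracle baseline subtraction is exact", {
  cond <- reactionConditions(5000, emax = 1.9)
  v <- variationConfig(sources = character(0), baseline = TRUE,
                       camera = FALSE)
  pl <- simulatePlate(cond, v, nReps = 4, seed = 31)
  expect_equal(baselineSubtract(pl),
               SummarizedExperiment::assay(pl, "amp"), tolerance = 1e-12)
})
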