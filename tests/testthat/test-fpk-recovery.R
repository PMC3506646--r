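test_that("observed efficiencies reproduce the generating chain", {
  ## pure doubling
  expect_true(all(abs(observedEfficiencies(2^(1:12), floor = 2)$eff - 2)
                  < 1e-12))
  ## noise-free engine trace: ratios equal the engine's efficiencies
  tr <- quietRun(50000, 1.9)
  amp <- ampFluorescence(tr)
  es <- observedEfficiencies(amp, floor = 17.5)
  expect_equal(es$eff, tr@eff[es$cycle], tolerance = 1e-12)
  expect_error(observedEfficiencies(rep(0.5, 20)), "noise floor")
})

test_that("bilinear fit round-trips noise-free curves", {
  ## primer-depleting curve: two-phase branch, exact recovery
  tr <- quietRun(50000, 1.9)
  fit <- fitBilinearToCurve(ampFluorescence(tr))
  expect_false(fit@singlePhase)
  expect_lt(abs(emaxEstimate(fit) - 1.9), 0.01)
  ## excess primers: single-phase branch selected, residual at least as
  ## low as the forced two-phase alternative
  t4 <- quietRun(50000, 1.95, primerX = 10)
  f4 <- fitBilinearToCurve(ampFluorescence(t4))
  expect_true(f4@singlePhase)
  expect_lt(abs(emaxEstimate(f4) - 1.95), 0.01)
  f4forced <- fitBilinearToCurve(ampFluorescence(t4), forceTwoPhase = TRUE)
  expect_lte(f4@fitQuality$rss, f4forced@fitQuality$rss + 1e-12)
  ## recovered first-phase parameters close to the generating values
  p <- systematicParams(1.95)
  expect_lt(abs(f4@params@beta1 - p@beta1) / abs(p@beta1), 0.05)
  expect_lt(abs(f4@params@beta2 - p@beta2) / abs(p@beta2), 0.05)
})

test_that("round-trip efficiency recovery holds across the efficiency range", {
  set.seed(19)
  errs <- vapply(runif(100, 1.5, 2), function(emax) {
    tr <- quietRun(30000, emax)
    fit <- tryCatch(fitBilinearToCurve(ampFluorescence(tr)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(emaxEstimate(fit) - emax)
  }, 0)
  expect_lt(median(errs, na.rm = TRUE), 0.005)
  expect_lt(mean(is.na(errs)), 0.1)
})

test_that("initial-signal back-propagation is exact without noise and recovers dilution ratios", {
  tr <- quietRun(50000, 1.9)
  fit <- estimateInitialSignal(ampFluorescence(tr),
                               fitBilinearToCurve(ampFluorescence(tr)))
  expect_lt(abs(fit@i0fHat / (1e-9 * 50000) - 1), 0.01)
  trA <- quietRun(20000, 1.9); trB <- quietRun(10000, 1.9)
  fA <- estimateInitialSignal(ampFluorescence(trA),
                              fitBilinearToCurve(ampFluorescence(trA)))
  fB <- estimateInitialSignal(ampFluorescence(trB),
                              fitBilinearToCurve(ampFluorescence(trB)))
  expect_lt(abs(fA@i0fHat / fB@i0fHat - 2), 0.02)
})

test_that("efficiency series tracks truth within the camera-noise propagation bound", {
  cond <- reactionConditions(50000, emax = 1.9)
  vc <- variationConfig(sources = character(0), baseline = FALSE,
                        camera = TRUE)
  set.seed(23)
  tr <- simulateReaction(cond, vc)
  es <- observedEfficiencies(tr@observed, floor = 17.5)
  truth <- tr@eff[es$cycle]
  bound <- 3 * 1.75 * sqrt(2) * es$eff / pmin(es$fPrev, 3900)
  expect_gt(mean(abs(es$eff - truth) <= bound), 0.97)
})
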