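test_that("trace matches an independently coded naive cycle loop", {
  cond <- reactionConditions(50000, emax = 1.9)
  draw <- makeDraw(50000, 1.9, g = 2.27)
  tr <- simulateReaction(cond, noVariation(), draw = draw)
  ## naive re-implementation
  p0 <- 260e-9 * 25e-6 * 6.02214076e23
  copies <- 50000; primers <- p0
  par <- draw@params; switched <- FALSE; fcR <- NA
  for (n in 1:60) {
    f <- 1e-9 * copies
    y <- if (switched) ln2Efficiency(f, par) else singlePhaseLn2(f, par)
    e <- min(max(exp(exp(y)), 1 + 1e-12), 2)
    dc <- min(copies * (e - 1), primers)
    side <- min(2.27 / 100 * primers, primers - dc)
    copies <- copies + dc
    primers <- primers - dc - side
    if (!switched && primers <= 0.1 * p0) {
      switched <- TRUE; fcR <- 1e-9 * copies
      par@fc <- fcR
    }
    expect_equal(tr@copies[n + 1], copies, tolerance = 1e-12)
    expect_equal(tr@primers[n + 1], primers, tolerance = 1e-12)
  }
  expect_equal(tr@fcRealized, fcR, tolerance = 1e-12)
})

test_that("primer ledger is conserved exactly on every cycle", {
  for (g in c(0, 2.27)) {
    tr <- quietRun(50000, 1.9, g = g)
    dCopies <- diff(tr@copies)
    dPrimers <- -diff(tr@primers)
    side <- dPrimers - dCopies
    ## exact up to double cancellation at the 1e12 primer-count scale
    expect_gt(min(side), -1e-2)
    if (g == 0) {
      expect_equal(max(abs(side)), 0, tolerance = 1e-3)
      ## total primers consumed = copies made
      expect_equal(tr@primers[1] - tr@primers[61],
                   tr@copies[61] - tr@copies[1], tolerance = 1e-6)
    } else {
      ## side loss is g% of the cycle-start primer pool (until exhaustion)
      pre <- which(tr@primers[-61] * 0.0227 <= tr@primers[-61] - dCopies)
      expect_equal(side[pre], 0.0227 * tr@primers[pre], tolerance = 1e-9)
    }
    expect_true(all(diff(tr@copies) >= 0))
    expect_true(all(diff(tr@primers) <= 0))
    expect_true(all(tr@primers >= 0))
  }
})

test_that("amplicon fluorescence is exactly fAmp times copies, capped by reagents", {
  tr <- quietRun(50000, 1.95)
  expect_identical(tr@fAmpFluor, 1e-9 * tr@copies)
  p0 <- initialPrimerCount(reactionConditions(50000, emax = 1.95))
  expect_lte(max(tr@copies), 50000 + p0)
  ## forced doubling: at maximal efficiency one cycle doubles the copies
  d2 <- makeDraw(100, 2.0)
  tr2 <- simulateReaction(reactionConditions(100, emax = 2), noVariation(),
                          draw = d2)
  expect_equal(tr2@copies[2], 200)
})

test_that("phase switch fires exactly at the 90% primer-consumption boundary", {
  tr <- quietRun(50000, 1.9)
  sw <- switchCycle(tr)
  expect_false(is.na(sw))
  p0 <- tr@p0
  expect_lte(tr@primers[sw + 1], 0.1 * p0)
  expect_gt(tr@primers[sw], 0.1 * p0)
  expect_equal(tr@fcRealized, tr@fAmpFluor[sw + 1])
  ## after the switch the plateau is reached within a few cycles
  amp <- ampFluorescence(tr)
  expect_lt(amp[sw + 3] / amp[60], 1.001)
  expect_gt(amp[sw + 3] / amp[60], 0.999)
})

test_that("Cq spacing between dilutions matches log(fold)/log(Emax)", {
  for (emax in c(1.85, 1.95)) {
    trA <- quietRun(40000, emax)
    trB <- quietRun(10000, emax)
    cqA <- cqValue(thresholdCq(ampFluorescence(trA), 100))
    cqB <- cqValue(thresholdCq(ampFluorescence(trB), 100))
    expect_lt(abs((cqB - cqA) - log(4) / log(emax)), 0.05)
  }
})

test_that("noise-free runs are identical whatever the seed", {
  cond <- reactionConditions(2000, emax = 1.9)
  set.seed(1); a <- simulateReaction(cond, noVariation())
  set.seed(999); b <- simulateReaction(cond, noVariation())
  expect_identical(a@observed, b@observed)
})

test_that("observation layer adds exactly a linear baseline and calibrated camera noise", {
  cond <- reactionConditions(5000, emax = 1.9, cycles = 60)
  ## baseline only: observed minus amplicon fluorescence is exactly linear
  vb <- variationConfig(sources = character(0), baseline = TRUE,
                        camera = FALSE)
  set.seed(3)
  tr <- simulateReaction(cond, vb)
  resid <- tr@observed - ampFluorescence(tr)
  expect_equal(resid, tr@draw@baselineIntercept +
                 tr@draw@baselineSlope * (1:60), tolerance = 1e-12)
  ## camera only: residual sd matches the configured 1.75 FU within 2%
  vc <- variationConfig(sources = character(0), baseline = FALSE,
                        camera = TRUE)
  pl <- simulatePlate(cond, vc, nReps = 200, seed = 8)
  resid <- SummarizedExperiment::assay(pl, "fluor") -
    SummarizedExperiment::assay(pl, "amp")
  expect_lt(abs(sd(resid) - 1.75) / 1.75, 0.02)
  ## camera off, baseline off: observed is the amplicon fluorescence
  tr0 <- simulateReaction(cond, noVariation())
  expect_identical(tr0@observed, ampFluorescence(tr0))
})

test_that("plates regenerate bit-identically from their seed", {
  cond <- reactionConditions(1000, emax = 1.9)
  a <- simulatePlate(cond, variationConfig(), nReps = 6, seed = 123)
  b <- simulatePlate(cond, variationConfig(), nReps = 6, seed = 123)
  expect_identical(SummarizedExperiment::assay(a, "fluor"),
                   SummarizedExperiment::assay(b, "fluor"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
})
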