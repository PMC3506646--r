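test_that("plate CSV round trip is lossless and shape-correct", {
  pl <- simulatePlate(reactionConditions(2000, emax = 1.9),
                      variationConfig(), nReps = 96, seed = 5)
  path <- tempfile(fileext = ".csv")
  writePlate(pl, path)
  expect_identical(length(readLines(path)), 61L)   # header + 60 cycles
  rd <- readPlate(path)
  expect_lt(max(abs(SummarizedExperiment::assay(rd, "fluor") -
                    SummarizedExperiment::assay(pl, "fluor")) /
                pmax(abs(SummarizedExperiment::assay(pl, "fluor")), 1)),
            1e-9)
  cd <- SummarizedExperiment::colData(rd)
  expect_identical(nrow(cd), 96L)
  expect_true(all(c("n0", "emaxI", "gI") %in% colnames(cd)))
  unlink(c(path, sub("\\.csv$", "_meta.csv", path)))
})

test_that("malformed plate files raise explicit parse errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Cycle,W001,W002", "1,10,11", "2,12"), path)
  expect_error(readPlate(path), "ragged.*row 3")
  writeLines(c("Cycle,W001,W001", "1,10,11", "2,12,13"), path)
  expect_error(readPlate(path), "duplicate well")
  unlink(path)
})

test_that("flat key=value configuration files configure both objects", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# a comment", "n0Mean = 1500", "emax = 1.88",
               "cycles = 45", "sources = E,i,s", "sigmaEmax = 0.02",
               "baseline = false"), path)
  cfg <- readSimConfig(path)
  expect_equal(cfg$cond@n0Mean, 1500)
  expect_equal(cfg$cond@emax, 1.88)
  expect_identical(cfg$cond@cycles, 45L)
  expect_identical(cfg$var@sources, c("E", "i", "s"))
  expect_equal(cfg$var@sigmaEmax, 0.02)
  expect_false(cfg$var@baseline)
  writeLines("nonsenseKey = 3", path)
  expect_error(readSimConfig(path), "unknown config key")
  unlink(path)
})

test_that("variance experiments are reproducible and degenerate correctly", {
  cond <- reactionConditions(20000, emax = 1.9)
  r0 <- runVarianceExperiment(character(0), nReps = 4, cond = cond,
                              seed = 2)
  expect_equal(r0$sdCqThreshold, 0, tolerance = 1e-8)
  expect_equal(r0$cvPlateau, 0, tolerance = 1e-10)
  a <- runVarianceExperiment("E", nReps = 8, cond = cond, seed = 4)
  b <- runVarianceExperiment("E", nReps = 8, cond = cond, seed = 4)
  expect_identical(a$cqThreshold, b$cqThreshold)
  expect_identical(a$plateau, b$plateau)
})

test_that("constant-efficiency endpoint interpolates and signals 'never'", {
  tr <- quietRun(50000, 1.9)
  ep <- constantEfficiencyEndpoint(tr)
  expect_gt(ep, 1); expect_lt(ep, 60)
  ## target efficiency is hit exactly at the interpolated endpoint
  expect_equal(efficiencyAtCycle(tr, ep), 1.9 - 0.01, tolerance = 1e-9)
  ## synthetic constant-efficiency trace: endpoint never reached
  flat <- tr
  flat@eff <- rep(1.9, 60)
  expect_true(is.na(constantEfficiencyEndpoint(flat)))
})

test_that("SDM displacement experiment returns equal heights for equal inputs", {
  d <- sdmDisplacementExperiment(c(24000, 24000, 24000), reps = 1)
  expect_lt(diff(range(d$sdmFluor)) / mean(d$sdmFluor), 1e-6)
  expect_identical(nrow(d), 3L)
})

test_that("the command-line generator writes the documented shapes", {
  out <- tempfile(fileext = ".csv")
  ## parameter mode: 6 x reps table
  runCli(c("--n0", "1000", "--reps", "7", "--seed", "3", "--output", "p",
           "--out", out))
  df <- read.csv(out)
  expect_identical(dim(df), c(6L, 8L))
  expect_identical(df$Parameter,
                   c("beta1", "beta2", "beta3", "c", "eta", "fc"))
  ## default mode: cycles x reps amplicon counts
  runCli(c("--n0", "1000", "--reps", "5", "--seed", "3", "--out", out))
  df <- read.csv(out)
  expect_identical(dim(df), c(60L, 6L))
  ## same seed twice -> identical files
  out2 <- tempfile(fileext = ".csv")
  runCli(c("--n0", "1000", "--reps", "5", "--seed", "3", "--out", out2))
  expect_identical(readLines(out), readLines(out2))
  ## invalid variation code names the valid ones
  expect_error(runCli(c("--n0", "10", "--out", out, "--variation", "Zz")),
               "valid codes")
  expect_error(runCli(c("--out", out)), "--n0")
  unlink(c(out, out2))
})

test_that("scaled-down variance batches agree within Monte-Carlo error", {
  cond <- reactionConditions(50000, emax = 1.9)
  big <- runVarianceExperiment("E", nReps = 96, cond = cond, seed = 61)
  small <- runVarianceExperiment("E", nReps = 32, cond = cond, seed = 62)
  seBig <- big$sdCqThreshold / sqrt(2 * 95)
  seSmall <- small$sdCqThreshold / sqrt(2 * 31)
  expect_lt(abs(big$sdCqThreshold - small$sdCqThreshold),
            3 * sqrt(seBig^2 + seSmall^2))
})
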