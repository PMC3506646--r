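## Experiment drivers: variance-component batches, dilution series,
## constant-efficiency endpoints and SDM displacement.

#' Variance-component experiment
#'
#' Simulates a batch of technical repeats with only the named variation
#' sources active and summarises the dispersion of the quantification
#' cycles and plateau levels.
#'
#' @param sources subset of c("En","E","i","p","s","a"); empty for a
#'   fully systematic batch.
#' @param nReps number of repeats (>= 2).
#' @param cond a \linkS4class{ReactionConditions} object.
#' @param var a \linkS4class{VariationConfig} carrying the magnitudes;
#'   its \code{sources} slot is replaced by \code{sources}.
#' @param seed integer seed for the batch.
#' @param threshold fixed Cq threshold (FU); the default 100 FU sits in
#'   the early exponential region (~2.5 percent of the standard plateau)
#'   for all study conditions.  \code{NULL} selects the SDM-height
#'   policy of [repeatSummary()] instead.
#' @return A list: the [repeatSummary()] fields plus \code{plate},
#'   \code{seed} and \code{sources}.
#' @examples
#' r <- runVarianceExperiment("E", nReps = 8,
#'                            cond = reactionConditions(50000, emax = 1.9),
#'                            seed = 11)
#' r$sdCqThreshold
#' @export
runVarianceExperiment <- function(sources, nReps = 96,
                                  cond = reactionConditions(50000,
                                                            emax = 1.9),
                                  var = variationConfig(), seed = NULL,
                                  threshold = 100) {
  stopifnot(nReps >= 2)
  var@sources <- as.character(sources)
  var@baseline <- FALSE  # kinetic sources only; observation layer off
  var@camera <- FALSE
  validObject(var)
  plate <- simulatePlate(cond, var, nReps = nReps, seed = seed)
  curves <- SummarizedExperiment::assay(plate, "fluor")  # no baseline here
  out <- repeatSummary(curves, threshold = threshold)
  out$plate <- plate
  out$seed <- seed
  out$sources <- sources
  out
}

#' Variance experiment with the observation layer on
#'
#' Like [runVarianceExperiment()] but with the baseline and/or camera
#' noise added and then removed again by oracle subtraction, so their
#' residual effect on the estimators can be studied in isolation.
#'
#' @inheritParams runVarianceExperiment
#' @param baseline,camera observation-layer switches.
#' @return As [runVarianceExperiment()].
#' @export
runObservationExperiment <- function(sources = character(0), nReps = 96,
                                     cond = reactionConditions(50000,
                                                               emax = 1.9),
                                     var = variationConfig(), seed = NULL,
                                     baseline = TRUE, camera = TRUE,
                                     threshold = 100) {
  var@sources <- as.character(sources)
  var@baseline <- baseline
  var@camera <- camera
  validObject(var)
  plate <- simulatePlate(cond, var, nReps = nReps, seed = seed)
  curves <- baselineSubtract(plate)
  out <- repeatSummary(curves, threshold = threshold)
  out$plate <- plate
  out$seed <- seed
  out$sources <- sources
  out
}

#' Twofold (or k-fold) dilution-series evaluation
#'
#' Simulates a dilution grid, analyses every reaction with the
#' full-process-kinetics fit and with threshold quantification cycles,
#' and reports: the mean initial-efficiency estimate, the mean adjacent
#' Cq spacing, the dilution factor recovered as
#' \code{(mean emaxHat)^(mean delta Cq)}, and the within-point
#' coefficients of variation of the two kinds of initial-copy estimates
#' (kinetic back-propagation vs Cq-based).
#'
#' @param startCopies copies at the most concentrated point.
#' @param fold dilution factor between adjacent points.
#' @param nPoints number of dilution points.
#' @param repsPerPoint repeats per point.
#' @param totalReactions optionally trim the batch to this many
#'   reactions (drops wells from the last point).
#' @param cond base \linkS4class{ReactionConditions} (its \code{n0Mean}
#'   is replaced per point).
#' @param var a \linkS4class{VariationConfig}.
#' @param seed integer seed.
#' @param floor noise floor for the kinetic fit (FU).
#' @param threshold fixed Cq threshold (FU), as in
#'   [runVarianceExperiment()].
#' @return A list with elements \code{meanEmaxHat}, \code{dilutionFactor},
#'   \code{cvFpkCopies}, \code{cvCqCopies}, \code{meanDeltaCq},
#'   \code{perPoint} (data.frame), \code{nFailed} and \code{seed}.
#' @export
runDilutionExperiment <- function(startCopies = 1e5, fold = 2, nPoints = 9,
                                  repsPerPoint = 89, totalReactions = 800,
                                  cond = reactionConditions(1e5,
                                                            emax = 1.95),
                                  var = variationConfig(), seed = NULL,
                                  floor = 10 * var@cameraSd,
                                  threshold = 100) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nPoints >= 2, repsPerPoint >= 2)
  n0s <- startCopies / fold^(seq_len(nPoints) - 1L)
  reps <- rep(repsPerPoint, nPoints)
  if (!is.null(totalReactions)) {
    excess <- sum(reps) - totalReactions
    if (excess > 0) reps[nPoints] <- reps[nPoints] - excess
    stopifnot(reps[nPoints] >= 2)
  }

  emaxHats <- vector("list", nPoints)
  fpkCopies <- vector("list", nPoints)
  curvesPerPoint <- vector("list", nPoints)
  fitsPerPoint <- vector("list", nPoints)
  nFailed <- 0L
  for (k in seq_len(nPoints)) {
    condK <- cond; condK@n0Mean <- n0s[k]
    plate <- simulatePlate(condK, var, nReps = reps[k])
    curves <- if (var@baseline) baselineSubtract(plate)
              else SummarizedExperiment::assay(plate, "fluor")
    curvesPerPoint[[k]] <- curves
    eh <- rep(NA_real_, reps[k]); ic <- rep(NA_real_, reps[k])
    fits <- vector("list", reps[k])
    for (i in seq_len(reps[k])) {
      est <- tryCatch({
        f <- fitBilinearToCurve(curves[, i], floor = floor)
        estimateInitialSignal(curves[, i], f, floor = floor)
      }, error = function(e) NULL)
      if (is.null(est)) { nFailed <- nFailed + 1L; next }
      eh[i] <- emaxEstimate(est)
      ic[i] <- est@i0fHat / cond@fAmp
      fits[[i]] <- est
    }
    emaxHats[[k]] <- eh
    fpkCopies[[k]] <- ic
    fitsPerPoint[[k]] <- fits
  }

  ## one fixed threshold across the whole series
  thr <- if (is.null(threshold)) {
    fits5 <- apply(curvesPerPoint[[1L]], 2L, fit5plm, simplify = FALSE)
    sdmThreshold(fits5)
  } else threshold
  cqs <- lapply(curvesPerPoint, function(m)
    apply(m, 2L, function(cv) cqValue(thresholdCq(cv, thr))))

  meanEmaxHat <- mean(unlist(emaxHats), na.rm = TRUE)
  meanCqs <- vapply(cqs, mean, 0, na.rm = TRUE)
  meanDeltaCq <- mean(diff(meanCqs))
  dilutionFactor <- meanEmaxHat^meanDeltaCq

  ## Cq-based copy estimates: N0hat proportional to meanEmaxHat^(-Cq)
  cqCopies <- lapply(cqs, function(v) meanEmaxHat^(-v))
  cvOf <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    sd(v) / mean(v)
  }
  perPoint <- data.frame(
    n0 = n0s, reps = reps,
    meanCq = meanCqs,
    meanEmaxHat = vapply(emaxHats, mean, 0, na.rm = TRUE),
    cvFpkCopies = vapply(fpkCopies, cvOf, 0),
    cvCqCopies = vapply(cqCopies, cvOf, 0))
  list(meanEmaxHat = meanEmaxHat,
       dilutionFactor = dilutionFactor,
       meanDeltaCq = meanDeltaCq,
       cvFpkCopies = mean(perPoint$cvFpkCopies, na.rm = TRUE),
       cvCqCopies = mean(perPoint$cvCqCopies, na.rm = TRUE),
       threshold = thr, perPoint = perPoint, nFailed = nFailed,
       seed = seed)
}

#' Constant-efficiency endpoint of a trace
#'
#' The model has no truly constant phase, only one of minimal decline;
#' the efficiency is considered constant until it has dropped by
#' \code{delta} (default 0.01) below its initial value.  The endpoint is
#' the fractional cycle, linearly interpolated between cycle efficiencies,
#' at which that happens; \code{NA} ("never") if it does not.
#'
#' @param trace a \linkS4class{ReactionTrace} (noise-free recommended).
#' @param delta efficiency decrease defining the endpoint.
#' @return Fractional cycle, or \code{NA} if the decline never reaches
#'   \code{delta}.
#' @examples
#' tr <- simulateReaction(reactionConditions(50000, emax = 1.9),
#'                        noVariation())
#' constantEfficiencyEndpoint(tr)   # about 20.3
#' @export
constantEfficiencyEndpoint <- function(trace, delta = 0.01) {
  stopifnot(is(trace, "ReactionTrace"))
  eff <- trace@eff
  target <- trace@draw@emaxI - delta
  below <- which(eff <= target)
  if (!length(below)) return(NA_real_)
  n <- below[1L]
  if (n == 1L) return(1)
  (n - 1) + (eff[n - 1L] - target) / (eff[n - 1L] - eff[n])
}

#' Efficiency at a fractional cycle
#'
#' Linear interpolation of the per-cycle efficiency trajectory.
#'
#' @param trace a \linkS4class{ReactionTrace}.
#' @param cycle fractional cycle position.
#' @return Interpolated efficiency.
#' @export
efficiencyAtCycle <- function(trace, cycle) {
  stopifnot(is(trace, "ReactionTrace"))
  stats::approx(seq_along(trace@eff), trace@eff, xout = cycle)$y
}

#' SDM displacement over a dilution series
#'
#' For each template input the mean fluorescence height of the SDM on
#' the (baseline-subtracted) curve.  On noise-free runs the height
#' increases strictly as the input decreases: the lower the initial copy
#' number, the higher up the curve the SDM sits.
#'
#' @param n0s initial copy numbers (>= 3 points).
#' @param reps repeats per point.
#' @param cond base conditions.
#' @param var a \linkS4class{VariationConfig}.
#' @param seed integer seed.
#' @return data.frame with \code{n0} and \code{sdmFluor} (mean per
#'   point), ordered as given.
#' @export
sdmDisplacementExperiment <- function(n0s, reps = 1,
                                      cond = reactionConditions(1e5,
                                                                emax = 1.95),
                                      var = noVariation(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(n0s) >= 3)
  heights <- vapply(n0s, function(n0) {
    condK <- cond; condK@n0Mean <- n0
    plate <- simulatePlate(condK, var, nReps = max(reps, 1))
    curves <- if (var@baseline) baselineSubtract(plate)
              else SummarizedExperiment::assay(plate, "fluor")
    mean(apply(curves, 2L, function(cv) sdmFluorescence(fit5plm(cv))))
  }, 0)
  data.frame(n0 = n0s, sdmFluor = heights)
}
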