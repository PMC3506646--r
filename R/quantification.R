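## Quantification-cycle estimation: spline-interpolated fixed threshold
## and the second-derivative maximum of a five-parameter logistic fit.

#' Threshold quantification cycle
#'
#' The fractional cycle at which the Forsythe-Malcolm-Moler cubic spline
#' through (cycle, fluorescence) first crosses the threshold from below.
#' An exact hit at an integer cycle returns that cycle.  A curve already
#' at or above the threshold at cycle 1 is flagged (the threshold sits
#' inside the baseline); a curve that never reaches it yields an
#' explicit missing value.
#'
#' @param curve baseline-subtracted fluorescence per cycle (numeric
#'   vector, cycle 1 first).
#' @param threshold threshold fluorescence (FU, > 0).
#' @return A \linkS4class{CqResult} with method "threshold".
#' @examples
#' thresholdCq(2^(1:12), threshold = 2^7)   # 7
#' @export
thresholdCq <- function(curve, threshold) {
  if (!is.numeric(curve) || any(!is.finite(curve)))
    stop("'curve' must be finite numeric fluorescence")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be a single positive number")
  C <- length(curve)
  res <- function(value, flag = "")
    new("CqResult", method = "threshold", value = value,
        thresholdUsed = threshold, flag = flag)
  if (curve[1L] >= threshold)
    return(res(1, flag = "threshold-inside-baseline"))
  sf <- splinefun(seq_len(C), curve, method = "fmm")
  for (k in seq_len(C - 1L)) {
    if (curve[k + 1L] >= threshold) {
      if (curve[k + 1L] == threshold) return(res(k + 1))
      root <- uniroot(function(x) sf(x) - threshold, c(k, k + 1L),
                      tol = 1e-9)$root
      return(res(root))
    }
  }
  res(NA_real_, flag = "no-crossing")
}

## 5PLM model function
.fivePLM <- function(x, fb, fmax, cInfl, bGrowth, gAsym)
  fb + fmax / (1 + exp(-(x - cInfl) / bGrowth))^gAsym

#' Evaluate a fitted five-parameter logistic model
#' @param p a \linkS4class{FivePLMParams} object.
#' @param x cycle positions.
#' @return Fitted fluorescence at \code{x}.
#' @export
predict5plm <- function(p, x) {
  stopifnot(is(p, "FivePLMParams"))
  .fivePLM(x, p@fb, p@fmax, p@cInfl, p@bGrowth, p@gAsym)
}

#' Fit the five-parameter logistic model to an amplification curve
#'
#' Levenberg-Marquardt least squares with multi-start initialisation: the
#' base fluorescence from the early cycles, the amplitude from the late
#' cycles, the centre from the cycle of the largest first difference, and
#' a small grid of growth-rate and asymmetry starting values; the start
#' with the lowest residual sum of squares wins.
#'
#' @param curve raw fluorescence per cycle (a sigmoidal rise; the plateau
#'   should be reached or nearly reached).
#' @param cycles cycle positions (default 1..length(curve)).
#' @return A \linkS4class{FivePLMParams} object.
#' @examples
#' truth <- fivePLMParams(fb = 100, fmax = 3000, cInfl = 25, bGrowth = 1.4,
#'                        gAsym = 0.8)
#' fit <- fit5plm(predict5plm(truth, 1:60))
#' @export
fit5plm <- function(curve, cycles = seq_along(curve)) {
  if (!is.numeric(curve) || any(!is.finite(curve)))
    stop("'curve' must be finite numeric fluorescence")
  C <- length(curve)
  if (C < 8L) stop("need at least 8 cycles to fit the 5PLM")
  fb0 <- mean(curve[seq_len(min(5L, C))])
  fmax0 <- max(mean(curve[seq.int(max(1L, C - 2L), C)]) - fb0,
               diff(range(curve)) * 0.5, 1e-6)
  d1 <- diff(curve)
  c0 <- cycles[which.max(d1)] + 0.5
  b0 <- max(fmax0 / (4 * max(d1)), 0.2)
  df <- data.frame(x = cycles, yy = curve)
  best <- NULL
  for (g0 in c(1, 0.3, 3)) for (bm in c(1, 0.5, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ fb + fmax / (1 + exp(-(x - cInfl) / bGrowth))^gAsym,
        data = df,
        start = list(fb = fb0, fmax = fmax0, cInfl = c0,
                     bGrowth = b0 * bm, gAsym = g0),
        lower = c(fb = -Inf, fmax = 1e-9, cInfl = min(cycles) - 10,
                  bGrowth = 0.05, gAsym = 0.01),
        upper = c(fb = Inf, fmax = Inf, cInfl = max(cycles) + 20,
                  bGrowth = 30, gAsym = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, coef = coef(fit))
    }
  }
  if (is.null(best))
    stop("5PLM fit failed to converge from every start")
  cf <- best$coef
  fivePLMParams(fb = cf[["fb"]], fmax = cf[["fmax"]], cInfl = cf[["cInfl"]],
                bGrowth = cf[["bGrowth"]], gAsym = cf[["gAsym"]],
                rss = best$rss)
}

#' Second-derivative-maximum quantification cycle
#'
#' The first positive maximum of the analytic second derivative of the
#' five-parameter logistic curve.  Writing \eqn{u = \exp(-(x - c)/b)},
#' the second derivative is proportional to
#' \eqn{u (g u - 1) (1 + u)^{-(g+2)}}, positive for \eqn{u > 1/g} and
#' maximal at the larger root of \eqn{g^2 u^2 - (3g + 1) u + 1 = 0}; the
#' SDM is therefore \eqn{c - b \ln u^*}.  For the symmetric logistic
#' (g = 1) this reduces to the classical \eqn{c - b \ln(2 + \sqrt 3)}.
#' The SDM always precedes the curve's inflection at \eqn{c + b \ln g}.
#'
#' @param p a \linkS4class{FivePLMParams} object.
#' @return A \linkS4class{CqResult} with method "sdm".
#' @examples
#' sdmCq(fivePLMParams(0, 3000, cInfl = 30, bGrowth = 1.5, gAsym = 1))
#' ## 30 - 1.5 * log(2 + sqrt(3))
#' @export
sdmCq <- function(p) {
  stopifnot(is(p, "FivePLMParams"))
  g <- p@gAsym
  disc <- (3 * g + 1)^2 - 4 * g^2
  uStar <- ((3 * g + 1) + sqrt(disc)) / (2 * g^2)
  if (!is.finite(uStar) || uStar <= 1 / g)
    return(new("CqResult", method = "sdm", value = NA_real_,
               thresholdUsed = NA_real_, flag = "no-positive-maximum"))
  new("CqResult", method = "sdm", value = p@cInfl - p@bGrowth * log(uStar),
      thresholdUsed = NA_real_, flag = "")
}

#' Fluorescence position of the SDM on the fitted curve
#'
#' The baseline-free height of the fitted curve at the SDM, used both
#' for the default threshold policy and for studying the upward
#' displacement of the SDM at low template input.
#'
#' @param p a \linkS4class{FivePLMParams} object.
#' @return Fitted fluorescence at the SDM minus the base fluorescence,
#'   or \code{NA} when the SDM is undefined.
#' @export
sdmFluorescence <- function(p) {
  cq <- sdmCq(p)
  if (is.na(cq@value)) return(NA_real_)
  predict5plm(p, cq@value) - p@fb
}

#' Default threshold from a set of repeats
#'
#' The recommended user-independent threshold: the fluorescence height of
#' the SDM of the repeat whose SDM sits lowest on its curve.
#'
#' @param fits list of \linkS4class{FivePLMParams}, one per repeat.
#' @return Threshold fluorescence (FU).
#' @export
sdmThreshold <- function(fits) {
  h <- vapply(fits, sdmFluorescence, 0)
  h <- h[is.finite(h) & h > 0]
  if (!length(h)) stop("no repeat has a defined SDM position")
  min(h)
}

#' Plateau of an amplification curve
#'
#' Operationally the mean of the final three baseline-subtracted cycles.
#'
#' @param curve baseline-subtracted fluorescence per cycle.
#' @param k number of terminal cycles averaged (default 3).
#' @return Plateau fluorescence (FU).
#' @export
plateauLevel <- function(curve, k = 3L) {
  C <- length(curve)
  mean(curve[seq.int(max(1L, C - k + 1L), C)])
}

#' Summaries over a set of technical repeats
#'
#' Fits the 5PLM to every repeat, derives SDM and threshold
#' quantification cycles (threshold policy: the lowest SDM fluorescence
#' position across the set, unless a fixed threshold is supplied) and the
#' plateau levels, and returns their dispersion summaries.
#'
#' @param curves cycles x repeats matrix of baseline-subtracted
#'   fluorescence.
#' @param threshold fixed threshold (FU) overriding the SDM-based policy,
#'   or \code{NULL} for the default policy.
#' @return A list: \code{sdCqThreshold}, \code{sdCqSdm},
#'   \code{cvPlateau}, \code{threshold}, the per-repeat vectors
#'   \code{cqThreshold}, \code{cqSdm}, \code{plateau}, and
#'   \code{nMissing} (repeats whose Cq was undefined and excluded).
#' @examples
#' pl <- simulatePlate(reactionConditions(5000, emax = 1.9),
#'                     variationConfig("E", baseline = FALSE, camera = FALSE),
#'                     nReps = 6, seed = 2)
#' repeatSummary(SummarizedExperiment::assay(pl, "amp"))$sdCqThreshold
#' @export
repeatSummary <- function(curves, threshold = NULL) {
  stopifnot(is.matrix(curves), ncol(curves) >= 2L)
  fits <- apply(curves, 2L, fit5plm, simplify = FALSE)
  cqSdm <- vapply(fits, function(f) cqValue(sdmCq(f)), 0)
  thr <- if (is.null(threshold)) sdmThreshold(fits) else threshold
  cqThr <- vapply(seq_len(ncol(curves)),
                  function(i) cqValue(thresholdCq(curves[, i], thr)), 0)
  plateau <- apply(curves, 2L, plateauLevel)
  nMissing <- sum(is.na(cqThr)) + sum(is.na(cqSdm))
  list(sdCqThreshold = sd(cqThr, na.rm = TRUE),
       sdCqSdm = sd(cqSdm, na.rm = TRUE),
       cvPlateau = sd(plateau) / mean(plateau),
       threshold = thr, cqThreshold = cqThr, cqSdm = cqSdm,
       plateau = plateau, nMissing = nMissing)
}
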