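#' @import methods
#' @importFrom stats rnorm rpois sd plogis splinefun uniroot coef
#'   setNames approx resid
NULL

## Avogadro's number, molecules per mole
.AVOGADRO <- 6.02214076e23

#' Parameters of the double-log bilinear efficiency model
#'
#' The decline of the cycle efficiency \eqn{E} with accumulating amplicon
#' fluorescence \eqn{F} is modelled on the double-log scale
#' \eqn{y = \ln\ln E} as a smooth join of two phases: a curved first phase
#' \eqn{y_1(F) = c + \beta_1 x + \beta_2 x^2} (with \eqn{x = F/100},
#' fluorescence expressed in hundreds of fluorescence units) describing the
#' self-limiting decline, and a linear second phase of slope \eqn{\beta_3}
#' that takes over at the phase-change fluorescence \eqn{F_c} when primers
#' are depleted.  The abruptness of the transition is governed by
#' \eqn{\eta}: the second phase enters through a softplus ramp of width
#' \eqn{|\eta|} (on the same scale) centred on \eqn{F_c}, so the joined
#' decline is monotone and its slope tends to \eqn{\beta_3}.
#'
#' The intercept \eqn{c} equals \eqn{\ln\ln E_{max}}, so the model value at
#' \eqn{F = 0} recovers the initial efficiency exactly.
#'
#' @slot beta1 first-phase slope (double-log units per 100 FU, typically < 0)
#' @slot beta2 first-phase curvature (double-log units per (100 FU)^2)
#' @slot beta3 second-phase slope (double-log units per 100 FU, < 0 and
#'   steeper than \code{beta1})
#' @slot c vertical offset; \code{exp(exp(c))} is the initial efficiency
#' @slot eta transition-abruptness parameter (100 FU); its magnitude is
#'   the width of the logistic join, its (negative) sign records that the
#'   transition accelerates the decline
#' @slot fc phase-change fluorescence (FU, > 0).  \code{NA} while a
#'   simulated reaction has not (yet) depleted its primers; the engine
#'   fills it in on the fly.
#'
#' @seealso [bilinearParams()], [ln2Efficiency()], [efficiencyAt()]
#' @export
setClass("BilinearParams",
  representation(beta1 = "numeric", beta2 = "numeric", beta3 = "numeric",
                 c = "numeric", eta = "numeric", fc = "numeric"))

setValidity("BilinearParams", function(object) {
  msg <- NULL
  for (s in c("beta1", "beta2", "beta3", "c", "eta"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(object@fc) != 1L)
    msg <- c(msg, "'fc' must have length 1")
  else if (!is.na(object@fc) && (!is.finite(object@fc) || object@fc <= 0))
    msg <- c(msg, "'fc' must be > 0 (or NA while undetermined)")
  if (is.null(msg) && object@beta3 >= min(0, object@beta1))
    msg <- c(msg, "'beta3' must be < min(0, beta1): the second phase declines faster")
  if (is.null(msg) && object@eta == 0)
    msg <- c(msg, "'eta' must be non-zero")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BilinearParams object
#'
#' @param beta1,beta2,beta3,c,eta,fc see [BilinearParams-class].
#' @return A \linkS4class{BilinearParams} object.
#' @examples
#' p <- bilinearParams(beta1 = -0.4, beta2 = -0.02, c = log(log(1.9)))
#' efficiencyAt(0, p)
#' @export
bilinearParams <- function(beta1, beta2, beta3 = -8.5, c, eta = -0.04,
                           fc = NA_real_) {
  new("BilinearParams", beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      beta3 = as.numeric(beta3), c = as.numeric(c), eta = as.numeric(eta),
      fc = as.numeric(fc))
}

setMethod("show", "BilinearParams", function(object) {
  cat("BilinearParams (double-log efficiency model, fluorescence unit 100 FU)\n")
  cat(sprintf("  beta1 = %.6g  beta2 = %.6g  beta3 = %.6g\n",
              object@beta1, object@beta2, object@beta3))
  cat(sprintf("  c     = %.6g  (Emax = %.4f)\n", object@c,
              exp(exp(object@c))))
  cat(sprintf("  eta   = %.6g  fc = %s FU\n", object@eta,
              if (is.na(object@fc)) "<unset>" else sprintf("%.1f", object@fc)))
})

#' Reaction conditions for a simulated qPCR run
#'
#' @slot n0Mean expected initial template copies per reaction
#' @slot emax initial reaction efficiency (fold change per cycle,
#'   1 < emax <= 2)
#' @slot cycles number of PCR cycles
#' @slot primerConc primer concentration in the final volume (nM)
#' @slot volume reaction volume (microlitre)
#' @slot fAmp fluorescence emitted by a single amplicon (FU)
#' @export
setClass("ReactionConditions",
  representation(n0Mean = "numeric", emax = "numeric", cycles = "integer",
                 primerConc = "numeric", volume = "numeric", fAmp = "numeric"))

setValidity("ReactionConditions", function(object) {
  msg <- NULL
  if (!(object@emax > 1 && object@emax <= 2))
    msg <- c(msg, "'emax' must satisfy 1 < emax <= 2")
  if (object@n0Mean <= 0) msg <- c(msg, "'n0Mean' must be > 0")
  if (object@cycles < 1L) msg <- c(msg, "'cycles' must be >= 1")
  if (object@primerConc <= 0) msg <- c(msg, "'primerConc' must be > 0")
  if (object@volume <= 0) msg <- c(msg, "'volume' must be > 0")
  if (object@fAmp <= 0) msg <- c(msg, "'fAmp' must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct reaction conditions
#'
#' Defaults mirror the standard assay the model was developed for: 60
#' cycles, 260 nM primers in 25 uL.  The single-amplicon fluorescence
#' default of 1e-9 FU places the primer-depletion ceiling of a 1x reaction
#' near 3900 FU, the magnitude of a typical SYBR-green plateau.
#'
#' @param n0Mean expected initial template copies.
#' @param emax initial efficiency (default 1.95).
#' @param cycles number of cycles (default 60).
#' @param primerConc primer concentration, nM (default 260).
#' @param volume reaction volume, uL (default 25).
#' @param fAmp single-amplicon fluorescence, FU (default 1e-9).
#' @return A \linkS4class{ReactionConditions} object.
#' @examples
#' reactionConditions(50000, emax = 1.9)
#' @export
reactionConditions <- function(n0Mean, emax = 1.95, cycles = 60,
                               primerConc = 260, volume = 25, fAmp = 1e-9) {
  new("ReactionConditions", n0Mean = as.numeric(n0Mean),
      emax = as.numeric(emax), cycles = as.integer(cycles),
      primerConc = as.numeric(primerConc), volume = as.numeric(volume),
      fAmp = as.numeric(fAmp))
}

#' Initial primer count of a reaction
#'
#' \code{primerConc * volume * Avogadro}, i.e. the number of primer
#' molecules pipetted into the well (260 nM in 25 uL is about 3.9e12).
#'
#' @param cond a \linkS4class{ReactionConditions} object.
#' @return Number of primer molecules.
#' @export
initialPrimerCount <- function(cond) {
  stopifnot(is(cond, "ReactionConditions"))
  cond@primerConc * 1e-9 * cond@volume * 1e-6 * .AVOGADRO
}

setMethod("show", "ReactionConditions", function(object) {
  cat(sprintf(paste0("ReactionConditions: N0 = %g copies, Emax = %.3f, ",
                     "%d cycles\n  primers %g nM in %g uL (P0 = %.3g), ",
                     "f = %g FU/amplicon\n"),
              object@n0Mean, object@emax, object@cycles, object@primerConc,
              object@volume, initialPrimerCount(object), object@fAmp))
})

#' Variance-component configuration
#'
#' Which sources of between-repeat and within-reaction variation are
#' active, and their magnitudes.  Source codes follow the generator
#' interface:
#' \describe{
#'   \item{"En"}{random error on each cycle's efficiency (constant
#'     relative sd \code{sigmaERel} on the increment \eqn{E-1})}
#'   \item{"E"}{between-repeat variation of the true initial efficiency
#'     (normal, sd \code{sigmaEmax}, truncated to (1, 2])}
#'   \item{"i"}{Poisson sampling of the initial template copies}
#'   \item{"p"}{primer pipetting variation (relative sd
#'     \code{sigmaPrimerRel} on the initial primer count)}
#'   \item{"s"}{side reactions: each cycle a percentage g of the remaining
#'     primers is lost to unspecific processes; g is drawn per repeat
#'     (normal, mean \code{sideGMean}, sd \code{sideGSd}, truncated >= 0)}
#'   \item{"a"}{kinetic variation: small relative jitter on the
#'     first-phase decline parameters beta1 and beta2}
#' }
#'
#' When both "E" and "s" are active the draws of the true initial
#' efficiency and of the side-loss rate are coupled through a Gaussian
#' copula with rank correlation \code{rhoCouple}, signed so that repeats
#' destined to emerge earlier (higher efficiency) lose fewer primers and
#' reach higher plateaus.
#'
#' The baseline (linear drift, per-repeat random intercept and slope) and
#' camera noise (additive, per-cycle) belong to the observation layer and
#' are switched by the logical slots \code{baseline} and \code{camera}.
#'
#' @slot sources character vector, subset of c("En","E","i","p","s","a")
#' @slot sigmaEmax sd of the true initial efficiency between repeats
#' @slot sigmaERel relative sd of the per-cycle efficiency error
#' @slot sigmaPrimerRel relative sd of the initial primer count
#' @slot sigmaKinetic relative sd of the per-repeat beta1/beta2 jitter
#' @slot baselineInterceptMean,baselineInterceptSd baseline intercept, FU
#' @slot baselineSlopeMean,baselineSlopeSd baseline slope, FU per cycle
#' @slot cameraSd camera noise sd, FU
#' @slot sideGMean,sideGSd side-reaction loss, percent of current primers
#'   per cycle
#' @slot rhoCouple rank correlation coupling efficiency and side loss
#' @slot baseline logical, add the linear baseline to observations
#' @slot camera logical, add camera noise to observations
#' @export
setClass("VariationConfig",
  representation(sources = "character", sigmaEmax = "numeric",
                 sigmaERel = "numeric", sigmaPrimerRel = "numeric",
                 sigmaKinetic = "numeric",
                 baselineInterceptMean = "numeric",
                 baselineInterceptSd = "numeric",
                 baselineSlopeMean = "numeric", baselineSlopeSd = "numeric",
                 cameraSd = "numeric", sideGMean = "numeric",
                 sideGSd = "numeric", rhoCouple = "numeric",
                 baseline = "logical", camera = "logical"))

.VAR_CODES <- c("En", "E", "i", "p", "s", "a")

setValidity("VariationConfig", function(object) {
  msg <- NULL
  bad <- setdiff(object@sources, .VAR_CODES)
  if (length(bad))
    msg <- c(msg, sprintf("unknown variation code(s) %s; valid codes are %s",
                          paste(sQuote(bad), collapse = ", "),
                          paste(sQuote(.VAR_CODES), collapse = ", ")))
  for (s in c("sigmaEmax", "sigmaERel", "sigmaPrimerRel", "sigmaKinetic",
              "baselineInterceptSd", "baselineSlopeSd", "cameraSd",
              "sideGSd"))
    if (slot(object, s) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", s))
  if (abs(object@rhoCouple) > 1)
    msg <- c(msg, "'rhoCouple' must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a variance-component configuration
#'
#' Defaults are the magnitudes estimated from (or bounded by) the
#' reference reaction dataset: camera noise sd 1.75 FU; baseline intercept
#' Normal(200, 70) FU and slope Normal(0.7, 0.2) FU/cycle; side-reaction
#' loss Normal(2.27, 0.47) percent of the remaining primers per cycle,
#' coupled to the initial-efficiency draw with rank correlation 0.46;
#' between-repeat sd of the true initial efficiency 0.01 (its upper
#' plausibility bound).  The per-cycle efficiency error (0.002 relative)
#' and the primer-pipetting and kinetic jitters (0.01 relative) have no
#' empirically printed value and are deliberately small.
#'
#' @param sources active variation sources; default all six.
#' @param sigmaEmax,sigmaERel,sigmaPrimerRel,sigmaKinetic magnitudes, see
#'   [VariationConfig-class].
#' @param baselineInterceptMean,baselineInterceptSd,baselineSlopeMean,baselineSlopeSd
#'   baseline model parameters.
#' @param cameraSd camera noise sd (FU).
#' @param sideGMean,sideGSd side-loss percentage per cycle.
#' @param rhoCouple rank correlation between efficiency and retained
#'   primers.
#' @param baseline,camera observation-layer switches.
#' @return A \linkS4class{VariationConfig} object.
#' @examples
#' ## initial-efficiency variation as the sole source, no observation noise
#' variationConfig(sources = "E", baseline = FALSE, camera = FALSE)
#' @export
variationConfig <- function(sources = .VAR_CODES,
                            sigmaEmax = 0.01, sigmaERel = 0.002,
                            sigmaPrimerRel = 0.01, sigmaKinetic = 0.01,
                            baselineInterceptMean = 200,
                            baselineInterceptSd = 70,
                            baselineSlopeMean = 0.7, baselineSlopeSd = 0.2,
                            cameraSd = 1.75, sideGMean = 2.27,
                            sideGSd = 0.47, rhoCouple = 0.46,
                            baseline = TRUE, camera = TRUE) {
  if (length(sources) == 1L && (identical(sources, "0") ||
                                identical(sources, character(0))))
    sources <- character(0)
  new("VariationConfig", sources = as.character(sources),
      sigmaEmax = sigmaEmax, sigmaERel = sigmaERel,
      sigmaPrimerRel = sigmaPrimerRel, sigmaKinetic = sigmaKinetic,
      baselineInterceptMean = baselineInterceptMean,
      baselineInterceptSd = baselineInterceptSd,
      baselineSlopeMean = baselineSlopeMean,
      baselineSlopeSd = baselineSlopeSd, cameraSd = cameraSd,
      sideGMean = sideGMean, sideGSd = sideGSd, rhoCouple = rhoCouple,
      baseline = baseline, camera = camera)
}

#' A configuration with every stochastic component switched off
#'
#' Convenience wrapper used for noise-free systematic runs.
#' @return A \linkS4class{VariationConfig} with no active sources and no
#'   observation noise.
#' @export
noVariation <- function()
  variationConfig(sources = character(0), baseline = FALSE, camera = FALSE)

setMethod("show", "VariationConfig", function(object) {
  src <- if (length(object@sources)) paste(object@sources, collapse = ",")
         else "<none>"
  cat(sprintf("VariationConfig: sources = {%s}, baseline = %s, camera = %s\n",
              src, object@baseline, object@camera))
  cat(sprintf("  sigmaEmax %.3g | sigmaERel %.3g | side g ~ N(%.2f, %.2f)%%",
              object@sigmaEmax, object@sigmaERel, object@sideGMean,
              object@sideGSd))
  cat(sprintf(" | rho %.2f\n", object@rhoCouple))
})

#' One repeat's realised random inputs
#'
#' @slot n0 realised initial template copies
#' @slot emaxI realised true initial efficiency
#' @slot gI realised side-reaction loss (percent of current primers per
#'   cycle)
#' @slot baselineIntercept,baselineSlope realised baseline (FU, FU/cycle)
#' @slot primerFactor multiplicative pipetting factor on the primer count
#' @slot params the repeat's \linkS4class{BilinearParams} (fc unset; the
#'   engine determines it on the fly)
#' @export
setClass("RepeatDraw",
  representation(n0 = "numeric", emaxI = "numeric", gI = "numeric",
                 baselineIntercept = "numeric", baselineSlope = "numeric",
                 primerFactor = "numeric", params = "BilinearParams"))

setValidity("RepeatDraw", function(object) {
  msg <- NULL
  if (object@n0 < 0 || object@n0 != round(object@n0))
    msg <- c(msg, "'n0' must be a non-negative integer count")
  if (!(object@emaxI > 1 && object@emaxI <= 2))
    msg <- c(msg, "'emaxI' must satisfy 1 < emaxI <= 2")
  if (object@gI < 0) msg <- c(msg, "'gI' must be >= 0")
  if (object@primerFactor < 0) msg <- c(msg, "'primerFactor' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RepeatDraw", function(object) {
  cat(sprintf(paste0("RepeatDraw: n0 = %g, emaxI = %.4f, g = %.3f%%/cycle, ",
                     "primerFactor = %.4f\n  baseline %.1f + %.2f*cycle FU\n"),
              object@n0, object@emaxI, object@gI, object@primerFactor,
              object@baselineIntercept, object@baselineSlope))
})

#' Full per-cycle record of one simulated reaction
#'
#' Index 1 of the per-cycle vectors is the pre-amplification state
#' (cycle 0); entry \code{n + 1} is the state at the end of cycle
#' \code{n}.  Reported curves are cycles 1..C.
#'
#' @slot copies amplicon count at the end of each cycle
#' @slot eff realised efficiency of each cycle (length C; entry n is the
#'   fold change applied during cycle n)
#' @slot primers remaining primer count at the end of each cycle
#' @slot fAmpFluor amplicon fluorescence, \code{fAmp * copies}
#' @slot observed observed fluorescence for cycles 1..C (amplicon +
#'   baseline + camera noise), or the amplicon fluorescence itself when
#'   the observation layer is off
#' @slot switchCycle cycle at which the primer-depletion phase switch
#'   fired, or \code{NA} if it never did
#' @slot fcRealized amplicon fluorescence at the switch cycle (FU)
#' @slot p0 initial primer count actually used
#' @slot draw the \linkS4class{RepeatDraw} that generated the trace
#' @export
setClass("ReactionTrace",
  representation(copies = "numeric", eff = "numeric", primers = "numeric",
                 fAmpFluor = "numeric", observed = "numeric",
                 switchCycle = "integer", fcRealized = "numeric",
                 p0 = "numeric", draw = "RepeatDraw"))

setMethod("show", "ReactionTrace", function(object) {
  C <- length(object@eff)
  cat(sprintf("ReactionTrace: %d cycles, n0 = %g, plateau = %.1f FU\n",
              C, object@copies[1], object@fAmpFluor[C + 1L]))
  if (is.na(object@switchCycle))
    cat("  self-limiting (primer-depletion switch never fired)\n")
  else
    cat(sprintf("  phase switch at cycle %d (Fc = %.1f FU)\n",
                object@switchCycle, object@fcRealized))
})

#' Five-parameter logistic (Richards) fit of an amplification curve
#'
#' \deqn{F(x) = f_b + \frac{f_{max}}{(1 + \exp(-(x - c)/b))^{g}}}
#' where \eqn{x} is the cycle number, \eqn{f_b} the base fluorescence,
#' \eqn{f_{max}} the amplitude of the plateau above base, \eqn{c} the
#' centre of the sigmoid, \eqn{b} the growth-rate parameter and \eqn{g}
#' the asymmetry parameter that moves the asymptote at which maximum
#' growth occurs (the curve inflects at \eqn{c + b\ln g}).
#'
#' @slot fb base fluorescence (FU)
#' @slot fmax plateau amplitude above base (FU, > 0)
#' @slot cInfl centre parameter (cycles)
#' @slot bGrowth growth-rate parameter (cycles, > 0)
#' @slot gAsym asymmetry parameter (> 0)
#' @slot rss residual sum of squares of the fit
#' @export
setClass("FivePLMParams",
  representation(fb = "numeric", fmax = "numeric", cInfl = "numeric",
                 bGrowth = "numeric", gAsym = "numeric", rss = "numeric"))

setValidity("FivePLMParams", function(object) {
  msg <- NULL
  if (object@fmax <= 0) msg <- c(msg, "'fmax' must be > 0")
  if (object@gAsym <= 0) msg <- c(msg, "'gAsym' must be > 0")
  if (object@bGrowth <= 0) msg <- c(msg, "'bGrowth' must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FivePLMParams object
#' @param fb,fmax,cInfl,bGrowth,gAsym,rss see [FivePLMParams-class].
#' @return A \linkS4class{FivePLMParams} object.
#' @export
fivePLMParams <- function(fb, fmax, cInfl, bGrowth, gAsym, rss = NA_real_)
  new("FivePLMParams", fb = fb, fmax = fmax, cInfl = cInfl,
      bGrowth = bGrowth, gAsym = gAsym, rss = rss)

setMethod("show", "FivePLMParams", function(object) {
  cat(sprintf(paste0("FivePLMParams: fb = %.2f, fmax = %.1f, c = %.2f, ",
                     "b = %.3f, g = %.3f (rss %.3g)\n"),
              object@fb, object@fmax, object@cInfl, object@bGrowth,
              object@gAsym, object@rss))
})

#' A quantification-cycle result
#'
#' @slot method "threshold" or "sdm"
#' @slot value fractional cycle; \code{NA} when the estimator is
#'   undefined for the curve (flag says why)
#' @slot thresholdUsed threshold fluorescence (FU) for the threshold
#'   method, \code{NA} for the SDM
#' @slot flag "" for a clean result, "no-crossing" when the threshold is
#'   never reached, "threshold-inside-baseline" when the curve already
#'   exceeds the threshold at cycle 1, "no-positive-maximum" for an SDM
#'   that does not exist in range
#' @export
setClass("CqResult",
  representation(method = "character", value = "numeric",
                 thresholdUsed = "numeric", flag = "character"))

setMethod("show", "CqResult", function(object) {
  cat(sprintf("CqResult [%s]: %s%s%s\n", object@method,
              ifelse(is.na(object@value), "undefined",
                     sprintf("%.3f", object@value)),
              if (!is.na(object@thresholdUsed))
                sprintf(" (threshold %.1f FU)", object@thresholdUsed) else "",
              if (nzchar(object@flag)) sprintf(" [%s]", object@flag) else ""))
})

#' Full-process-kinetics estimate recovered from an observed curve
#'
#' @slot emaxHat estimated initial efficiency, \code{exp(exp(c_hat))}
#' @slot params fitted \linkS4class{BilinearParams}
#' @slot i0fHat estimated initial amplicon fluorescence (FU); divide by
#'   the single-amplicon fluorescence to obtain a copy estimate
#' @slot singlePhase logical, whether the single-phase model was selected
#'   (excess-primer curves with no depletion phase)
#' @slot fitQuality list with the residual sum of squares, number of
#'   efficiency points used, and convergence diagnostics
#' @export
setClass("FPKEstimate",
  representation(emaxHat = "numeric", params = "BilinearParams",
                 i0fHat = "numeric", singlePhase = "logical",
                 fitQuality = "list"))

setValidity("FPKEstimate", function(object) {
  if (!is.na(object@emaxHat) && object@emaxHat <= 1)
    "'emaxHat' must be > 1" else TRUE
})

setMethod("show", "FPKEstimate", function(object) {
  cat(sprintf("FPKEstimate: emaxHat = %.4f (%s model)%s\n", object@emaxHat,
              if (object@singlePhase) "single-phase" else "two-phase",
              if (object@emaxHat > 2.05) "  [flag: emaxHat > 2.05]" else ""))
  if (!is.na(object@i0fHat))
    cat(sprintf("  i0fHat = %.3g FU, rss = %.3g on %d efficiency points\n",
                object@i0fHat, object@fitQuality$rss, object@fitQuality$n))
})

#' Accessor generics
#'
#' Small accessors for the estimate classes so downstream code never
#' touches slots directly.
#' @param object an object of the documented classes.
#' @return The corresponding scalar value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cqValue", function(object) standardGeneric("cqValue"))
#' @rdname accessors
#' @export
setMethod("cqValue", "CqResult", function(object) object@value)

#' @rdname accessors
#' @export
setGeneric("emaxEstimate", function(object) standardGeneric("emaxEstimate"))
#' @rdname accessors
#' @export
setMethod("emaxEstimate", "FPKEstimate", function(object) object@emaxHat)

#' @rdname accessors
#' @export
setGeneric("switchCycle", function(object) standardGeneric("switchCycle"))
#' @rdname accessors
#' @export
setMethod("switchCycle", "ReactionTrace", function(object) object@switchCycle)

#' @rdname accessors
#' @export
setGeneric("ampFluorescence",
           function(object) standardGeneric("ampFluorescence"))

#' Amplicon fluorescence of a trace, cycles 1..C
#' @rdname accessors
#' @export
setMethod("ampFluorescence", "ReactionTrace",
          function(object) object@fAmpFluor[-1L])

#' @rdname accessors
#' @export
setGeneric("efficiencies", function(object) standardGeneric("efficiencies"))
#' @rdname accessors
#' @export
setMethod("efficiencies", "ReactionTrace", function(object) object@eff)
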