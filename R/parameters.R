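## Parameter engine: systematic bilinear parameters from (N0, Emax) and
## per-repeat random draws of every variation source.

## Link coefficients tying the first-phase decline parameters to the
## initial efficiency.  beta1 is linear in Emax, beta2 linear in beta1;
## both links were calibrated once against the model's deterministic
## anchors (constant-efficiency endpoint 20.3 and E(21.3) = 1.88 at
## Emax = 1.90, SDM 25.6 / 26.7 at Emax = 1.95, both with N0 = 50000).
## The values below are frozen; see the methods vignette.
.LINK_DEFAULTS <- list(
  eq6 = c(-1.26051433074757, 0.62857145166542),    # beta1 = a0 + a1 * Emax
  eq7 = c(-8.79272656757787e-05, -0.00551515131252238), # beta2 = b0 + b1 * beta1
  beta3Const = -8.5,
  etaConst = -0.04
)

#' Coefficients linking initial efficiency to the decline parameters
#'
#' The systematic first-phase slope is an affine function of the initial
#' efficiency, and the curvature an affine function of that slope; the
#' second-phase slope and the transition abruptness are constants (-8.5
#' and -0.04 on the model's internal fluorescence scale of 100 FU).  The package ships one calibrated coefficient
#' set; pass a modified copy to the drawing functions to emulate a
#' different assay.
#'
#' @param eq6 numeric(2), intercept and slope of the Emax -> beta1 link.
#' @param eq7 numeric(2), intercept and slope of the beta1 -> beta2 link.
#' @param beta3Const second-phase slope constant.
#' @param etaConst transition-abruptness constant.
#' @return A list with the four components above.
#' @examples
#' linkCoefficients()
#' @export
linkCoefficients <- function(eq6 = .LINK_DEFAULTS$eq6,
                             eq7 = .LINK_DEFAULTS$eq7,
                             beta3Const = .LINK_DEFAULTS$beta3Const,
                             etaConst = .LINK_DEFAULTS$etaConst) {
  stopifnot(length(eq6) == 2L, length(eq7) == 2L,
            is.finite(eq6), is.finite(eq7),
            is.finite(beta3Const), beta3Const < 0, is.finite(etaConst),
            etaConst != 0)
  list(eq6 = as.numeric(eq6), eq7 = as.numeric(eq7),
       beta3Const = as.numeric(beta3Const), etaConst = as.numeric(etaConst))
}

.checkEmax <- function(emax) {
  if (!is.numeric(emax) || length(emax) != 1L || !is.finite(emax) ||
      emax <= 1 || emax > 2)
    stop("'emax' must be a single value with 1 < emax <= 2")
  emax
}

#' Systematic first-phase slope for a given initial efficiency
#'
#' Deterministic link: reactions with a lower initial efficiency attenuate
#' faster (more negative slope).
#'
#' @param emax initial efficiency, 1 < emax <= 2.
#' @param coef link coefficients, see [linkCoefficients()].
#' @return The first-phase slope beta1 (per 100 FU).
#' @examples
#' deriveFirstPhaseSlope(1.9)
#' @export
deriveFirstPhaseSlope <- function(emax, coef = linkCoefficients()) {
  .checkEmax(emax)
  coef$eq6[1] + coef$eq6[2] * emax
}

#' Systematic first-phase curvature for a given first-phase slope
#'
#' Deterministic link from the slope; over the inhibition-spanning range
#' of initial efficiencies the curvature changes sign, shifting the
#' decline profile from convex (high efficiency) over straight to concave
#' (strong inhibition).  The curvature depends on the initial efficiency
#' only through the slope and is independent of the template input.
#'
#' @param beta1 first-phase slope as returned by
#'   [deriveFirstPhaseSlope()].
#' @param coef link coefficients.
#' @return The curvature beta2 (per (100 FU)^2).
#' @export
deriveCurvature <- function(beta1, coef = linkCoefficients()) {
  if (!is.numeric(beta1) || length(beta1) != 1L || !is.finite(beta1) ||
      beta1 >= 0)
    stop("'beta1' must be a single negative finite number")
  coef$eq7[1] + coef$eq7[2] * beta1
}

#' Systematic bilinear parameters for a given initial efficiency
#'
#' Composes the two links and derives the intercept \code{c = log(log(emax))}
#' so that the model value at zero fluorescence recovers \code{emax}
#' exactly.  \code{fc} is left unset: the engine determines it on the fly
#' when 90 percent of the primers have been consumed.
#'
#' @inheritParams deriveFirstPhaseSlope
#' @return A \linkS4class{BilinearParams} object.
#' @examples
#' systematicParams(1.95)
#' @export
systematicParams <- function(emax, coef = linkCoefficients()) {
  b1 <- deriveFirstPhaseSlope(emax, coef)
  b2 <- deriveCurvature(b1, coef)
  bilinearParams(beta1 = b1, beta2 = b2, beta3 = coef$beta3Const,
                 c = log(log(emax)), eta = coef$etaConst, fc = NA_real_)
}

## Truncated-normal draw by rejection, preserving the latent z when
## given.  Returns list(value, rejects).
.truncNorm <- function(mean, sd, lower, upper, z = NULL) {
  rejects <- 0L
  if (sd == 0) return(list(value = mean, rejects = 0L))
  repeat {
    zz <- if (is.null(z)) rnorm(1L) else z
    v <- mean + sd * zz
    if (v > lower && v <= upper) return(list(value = v, rejects = rejects))
    rejects <- rejects + 1L
    z <- NULL  # after a rejection, redraw
  }
}

#' Draw one repeat's random inputs
#'
#' Realises every active variation source for a single technical repeat:
#' Poisson template sampling ("i"), the true initial efficiency ("E",
#' normal truncated to (1, 2]), the side-reaction loss rate ("s", normal
#' truncated at zero), primer pipetting ("p"), the kinetic beta1/beta2
#' jitter ("a"), and the baseline intercept/slope when the observation
#' baseline is on.  When both "E" and "s" are active their latent normals
#' are drawn from a bivariate Gaussian whose correlation is chosen so the
#' rank correlation between efficiency and side loss is
#' \code{-rhoCouple}: early-emerging repeats (high efficiency) lose fewer
#' primers and reach higher plateaus.
#'
#' With every source off the draw reproduces the systematic values
#' exactly.  All randomness comes from R's global stream; seed the
#' session (or pass \code{seed} to the plate-level functions) for
#' reproducibility.
#'
#' @param cond a \linkS4class{ReactionConditions} object.
#' @param var a \linkS4class{VariationConfig} object.
#' @param coef link coefficients, see [linkCoefficients()].
#' @return A \linkS4class{RepeatDraw} object.  Truncation events are
#'   recorded in the \code{"truncations"} attribute.
#' @examples
#' set.seed(1)
#' drawRepeatParameters(reactionConditions(50000), variationConfig())
#' @export
drawRepeatParameters <- function(cond, var, coef = linkCoefficients()) {
  stopifnot(is(cond, "ReactionConditions"), is(var, "VariationConfig"))
  validObject(cond); validObject(var)
  src <- var@sources
  truncations <- 0L

  ## 1. template copies
  n0 <- if ("i" %in% src) rpois(1L, cond@n0Mean) else round(cond@n0Mean)

  ## 2. latent normals for (emax, side loss); Gaussian copula when coupled
  wantE <- "E" %in% src && var@sigmaEmax > 0
  wantS <- "s" %in% src && var@sideGSd >= 0
  if (wantE || ("s" %in% src)) {
    if (wantE && "s" %in% src && var@rhoCouple != 0) {
      ## latent correlation giving the requested Spearman rank correlation
      rho <- 2 * sin(pi * var@rhoCouple / 6)
      z1 <- rnorm(1L)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1L)
      ## sign: high efficiency -> low side loss
      z2 <- -z2
    } else {
      z1 <- if (wantE) rnorm(1L) else 0
      z2 <- if ("s" %in% src) rnorm(1L) else 0
    }
  }
  emaxI <- cond@emax
  if (wantE) {
    tn <- .truncNorm(cond@emax, var@sigmaEmax, 1, 2, z = z1)
    emaxI <- tn$value
    truncations <- truncations + tn$rejects
  }
  gI <- 0
  if ("s" %in% src) {
    tn <- .truncNorm(var@sideGMean, var@sideGSd, 0, Inf, z = z2)
    gI <- tn$value
    truncations <- truncations + tn$rejects
  }

  ## 3. primer pipetting
  primerFactor <- if ("p" %in% src)
    max(0, 1 + rnorm(1L, 0, var@sigmaPrimerRel)) else 1

  ## 4. systematic kinetics for this repeat's efficiency, plus jitter
  b1 <- deriveFirstPhaseSlope(emaxI, coef)
  b2 <- deriveCurvature(b1, coef)
  if ("a" %in% src && var@sigmaKinetic > 0) {
    b1 <- b1 * (1 + rnorm(1L, 0, var@sigmaKinetic))
    b2 <- b2 * (1 + rnorm(1L, 0, var@sigmaKinetic))
    if (b1 >= 0) b1 <- -1e-6  # keep the decline a decline
  }
  params <- bilinearParams(beta1 = b1, beta2 = b2, beta3 = coef$beta3Const,
                           c = log(log(emaxI)), eta = coef$etaConst)

  ## 5. baseline
  if (var@baseline) {
    bi <- rnorm(1L, var@baselineInterceptMean, var@baselineInterceptSd)
    bs <- rnorm(1L, var@baselineSlopeMean, var@baselineSlopeSd)
  } else {
    bi <- 0; bs <- 0
  }

  out <- new("RepeatDraw", n0 = as.numeric(n0), emaxI = emaxI, gI = gI,
             baselineIntercept = bi, baselineSlope = bs,
             primerFactor = primerFactor, params = params)
  attr(out, "truncations") <- truncations
  out
}
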