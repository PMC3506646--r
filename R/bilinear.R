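## Double-log bilinear efficiency model.
##
## All model evaluation happens on fluorescence expressed in units of
## 100 FU (F / 100); the stored coefficients are on that scale.  The two
## phases are joined by a softplus ramp of width |eta| centred on fc: the
## second-phase correction is non-positive and monotone, so the joined
## model is non-increasing for every valid parameter set, its slope
## approaches beta3 beyond the transition, and the value at F = 0 is c up
## to a factor exp(-fc/|eta|) (identically zero in double precision for
## any realistic fc).

.FLUOR_SCALE <- 100  # FU per internal fluorescence unit

## First-phase quadratic with a monotonicity guard: for concave decline
## profiles (beta2 > 0) the parabola has a vertex beyond which it would
## rise again; the decline is frozen at its minimum instead, so the
## model is non-increasing in fluorescence for every parameter set.
.phase1 <- function(x, p) {
  if (p@beta2 > 0) {
    xv <- -p@beta1 / (2 * p@beta2)
    x <- pmin(x, xv)
  }
  p@c + p@beta1 * x + p@beta2 * x^2
}

## derivative of the (clamped) first phase
.phase1Slope <- function(x, p) {
  if (p@beta2 > 0) {
    xv <- -p@beta1 / (2 * p@beta2)
    if (x >= xv) return(0)
  }
  p@beta1 + 2 * p@beta2 * x
}

.checkFluor <- function(fPrev) {
  if (!is.numeric(fPrev) || any(!is.finite(fPrev)))
    stop("'fPrev' must be finite numeric fluorescence (FU)")
  if (any(fPrev < 0))
    stop("'fPrev' must be >= 0 (baseline-subtracted fluorescence)")
  invisible(fPrev)
}

#' Double-log efficiency as a function of the previous cycle's fluorescence
#'
#' Evaluates \eqn{y = \ln\ln E} of the bilinear model at baseline-
#' subtracted fluorescence \code{fPrev}.  With \code{fc} unset (\code{NA})
#' the reaction is treated as purely self-limiting and only the quadratic
#' first phase applies (see [singlePhaseLn2()]).
#'
#' @param fPrev baseline-subtracted fluorescence of the previous cycle
#'   (FU, >= 0); vectorised.
#' @param p a \linkS4class{BilinearParams} object.
#' @return Double-log efficiency, same length as \code{fPrev}.
#' @examples
#' p <- bilinearParams(beta1 = -0.44, beta2 = -0.01, c = log(log(1.9)),
#'                     fc = 3500)
#' ln2Efficiency(0, p)        # log(log(1.9))
#' @seealso [efficiencyAt()], [singlePhaseLn2()]
#' @export
ln2Efficiency <- function(fPrev, p) {
  stopifnot(is(p, "BilinearParams"))
  validObject(p)
  .checkFluor(fPrev)
  x <- fPrev / .FLUOR_SCALE
  y1 <- .phase1(x, p)
  if (is.na(p@fc))
    return(y1)
  xc <- p@fc / .FLUOR_SCALE
  h <- abs(p@eta)
  ## softplus join: adds a non-positive, monotonically steepening
  ## correction whose asymptotic slope takes the decline to beta3; the
  ## model value stays non-increasing for every valid parameter set
  d1c <- .phase1Slope(xc, p)
  sp <- ifelse((x - xc) / h > 30, x - xc,
               h * log1p(exp(pmin((x - xc) / h, 30))))
  y1 + (p@beta3 - d1c) * sp
}

#' Cycle efficiency as a function of the previous cycle's fluorescence
#'
#' \code{exp(exp(y))} of [ln2Efficiency()], clipped to (1, 2]: values are
#' kept strictly above 1 (an efficiency at or below 1 is meaningless in
#' this model and would leave downstream double logs undefined) and at or
#' below the theoretical doubling limit.
#'
#' @inheritParams ln2Efficiency
#' @return Cycle efficiency E, 1 < E <= 2.
#' @examples
#' p <- bilinearParams(beta1 = -0.44, beta2 = -0.01, c = log(log(1.9)))
#' efficiencyAt(0, p)  # 1.9
#' @export
efficiencyAt <- function(fPrev, p) {
  e <- exp(exp(ln2Efficiency(fPrev, p)))
  pmin(pmax(e, 1 + 1e-12), 2)
}

#' Single-phase (self-limiting) double-log efficiency
#'
#' The reduced model for excess-primer reactions in which the
#' primer-depletion phase never occurs: the quadratic first phase alone,
#' \eqn{y = c + \beta_1 x + \beta_2 x^2}.  Identical to
#' [ln2Efficiency()] with the transition pushed beyond the plateau.
#'
#' @inheritParams ln2Efficiency
#' @return Double-log efficiency.
#' @export
singlePhaseLn2 <- function(fPrev, p) {
  stopifnot(is(p, "BilinearParams"))
  .checkFluor(fPrev)
  .phase1(fPrev / .FLUOR_SCALE, p)
}
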