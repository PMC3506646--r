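## Full-process-kinetics recovery: per-cycle efficiencies from an
## observed curve, a weighted bilinear fit on the double-log scale, and
## back-propagation of the initial amplicon fluorescence.

#' Observed per-cycle efficiencies of a curve
#'
#' The efficiency of cycle n is the fold increase in baseline-subtracted
#' fluorescence, \eqn{E_n = F_n / F_{n-1}}.  The series is only defined
#' where the fluorescence has cleared the noise floor; each value is
#' paired with the previous cycle's fluorescence for regression on the
#' double-log scale.
#'
#' @param curve baseline-subtracted fluorescence per cycle.
#' @param floor noise floor (FU); cycles whose previous fluorescence is
#'   at or below it are excluded.  The default, ten times the camera
#'   noise sd, is a simple proxy for the data-driven end of the ground
#'   phase.
#' @return A data.frame with columns \code{cycle}, \code{fPrev} and
#'   \code{eff}.
#' @examples
#' observedEfficiencies(2^(1:12), floor = 2)   # all efficiencies 2
#' @export
observedEfficiencies <- function(curve, floor = 17.5) {
  if (!is.numeric(curve) || any(!is.finite(curve)))
    stop("'curve' must be finite numeric fluorescence")
  C <- length(curve)
  n <- 2:C
  keep <- curve[n - 1L] > floor & curve[n] > floor
  if (!any(keep))
    stop("no cycles above the noise floor; cannot form efficiency series")
  data.frame(cycle = n[keep], fPrev = curve[n - 1L][keep],
             eff = curve[n][keep] / curve[n - 1L][keep])
}

## first-phase quadratic with the same vertex clamp as the generator
.quadY <- function(x, cc, b1, b2) {
  if (length(b2) == 1L && is.finite(b2) && b2 > 0 && b1 < 0)
    x <- pmin(x, -b1 / (2 * b2))
  cc + b1 * x + b2 * x^2
}

## bilinear model on the double-log scale for nlsLM (x on the internal
## fluorescence scale); same softplus join as the generator
.bilinY <- function(x, cc, b1, b2, xc, b3, h) {
  y1 <- .quadY(x, cc, b1, b2)
  d1c <- if (b2 > 0 && xc >= -b1 / (2 * b2)) 0 else b1 + 2 * b2 * xc
  sp <- ifelse((x - xc) / h > 30, x - xc,
               h * log1p(exp(pmin((x - xc) / h, 30))))
  y1 + (b3 - d1c) * sp
}

#' Fit the bilinear efficiency model to an observed curve
#'
#' Regresses \eqn{\ln\ln E_n} on the previous cycle's fluorescence by
#' Levenberg-Marquardt least squares, weighted proportionally to the
#' fluorescence (additive camera noise makes the double-log response
#' strongly heteroskedastic at low fluorescence).  The second-phase slope
#' and the transition width are held at their model constants; the free
#' parameters are the intercept, the two first-phase coefficients and the
#' phase-change fluorescence.  When the two-phase fit does not improve on
#' the single-phase (excess-primer) model, or places the transition
#' outside the data, the single-phase fit is returned.
#'
#' The initial-efficiency estimate is the double exponential of the
#' fitted intercept.
#'
#' @param curve baseline-subtracted fluorescence per cycle.
#' @param floor noise floor passed to [observedEfficiencies()].
#' @param coef link coefficients supplying the second-phase constants.
#' @param forceTwoPhase logical; keep the two-phase fit even when the
#'   single-phase model fits better (diagnostic use).
#' @return An \linkS4class{FPKEstimate} (its \code{i0fHat} slot is filled
#'   by [estimateInitialSignal()]).
#' @examples
#' tr <- simulateReaction(reactionConditions(50000, emax = 1.9),
#'                        noVariation())
#' emaxEstimate(fitBilinearToCurve(ampFluorescence(tr)))
#' @export
fitBilinearToCurve <- function(curve, floor = 17.5,
                               coef = linkCoefficients(),
                               forceTwoPhase = FALSE) {
  es <- observedEfficiencies(curve, floor)
  ## the dead-flat tail carries no kinetic information but, with additive
  ## noise, produces wild double-log values; keep the rise and the
  ## transition, drop everything after the first cycle whose increment
  ## has collapsed below 2 percent of the curve height
  inc <- diff(curve)
  stopAt <- which(inc < 0.02 * max(curve))
  stopAt <- stopAt[stopAt > which.max(inc)]
  cut <- if (length(stopAt)) stopAt[1L] else Inf
  ## steep depletion curves can leave a very short window; extend into
  ## the transition (at most two cycles) before giving up
  for (ext in 0:2) {
    esk <- es[es$cycle <= cut + ext & es$eff > 1, , drop = FALSE]
    if (nrow(esk) >= 8L) break
  }
  es <- esk
  if (nrow(es) < 8L)
    stop("fewer than 8 usable efficiency points above the noise floor")
  df <- data.frame(x = es$fPrev / .FLUOR_SCALE, y = log(log(es$eff)),
                   w = es$fPrev)
  b3 <- coef$beta3Const
  h <- abs(coef$etaConst)
  cc0 <- max(df$y)
  b1x <- stats::lm(y ~ x, data = df, weights = w)$coef
  b10 <- min(unname(b1x[2]), -1e-3)

  single <- tryCatch(
    minpack.lm::nlsLM(y ~ .quadY(x, cc, b1, b2), data = df, weights = w,
                      start = list(cc = cc0, b1 = b10, b2 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(single)) stop("single-phase bilinear fit failed to converge")
  rss1 <- sum(resid(single)^2 * df$w) / sum(df$w)

  xcTop <- max(df$x)
  two <- NULL
  rss2 <- Inf
  for (xc0 in c(0.7, 0.85, 0.95, 1) * xcTop) {
    cand <- tryCatch(
      minpack.lm::nlsLM(y ~ .bilinY(x, cc, b1, b2, xc, b3, h), data = df,
                        weights = w,
                        start = list(cc = cc0, b1 = b10, b2 = 0, xc = xc0),
                        lower = c(cc = -Inf, b1 = -Inf, b2 = -Inf,
                                  xc = min(df$x)),
                        upper = c(cc = Inf, b1 = 0, b2 = Inf,
                                  xc = 2 * xcTop),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rssC <- sum(resid(cand)^2 * df$w) / sum(df$w)
    if (rssC < rss2) { two <- cand; rss2 <- rssC }
  }
  xcHat <- if (is.null(two)) Inf else stats::coef(two)[["xc"]]

  ## the transition is considered identified when it lies no further
  ## than one ramp width beyond the last analysed point
  useTwo <- !is.null(two) && (forceTwoPhase ||
                              (rss2 < rss1 && xcHat <= xcTop + h))
  if (useTwo) {
    cf <- stats::coef(two)
    params <- bilinearParams(beta1 = min(cf[["b1"]], -1e-9),
                             beta2 = cf[["b2"]],
                             beta3 = b3, c = cf[["cc"]], eta = coef$etaConst,
                             fc = cf[["xc"]] * .FLUOR_SCALE)
    rss <- rss2
  } else {
    cf <- stats::coef(single)
    params <- bilinearParams(beta1 = min(cf[["b1"]], -1e-9),
                             beta2 = cf[["b2"]],
                             beta3 = b3, c = cf[["cc"]], eta = coef$etaConst,
                             fc = NA_real_)
    rss <- rss1
  }
  new("FPKEstimate", emaxHat = exp(exp(params@c)), params = params,
      i0fHat = NA_real_, singlePhase = !useTwo,
      fitQuality = list(rss = rss, n = nrow(df),
                        rssSingle = rss1, rssTwo = rss2))
}

#' Back-propagated initial amplicon fluorescence
#'
#' Divides the observed fluorescence of each early analysed cycle by the
#' cumulative product of model efficiencies evaluated along the curve,
#' \eqn{\hat{I_0 f} = \mathrm{mean}_n\, F_n / \prod_{c \le n} \hat E_c},
#' and averages over an early-cycle window.  The estimator assumes all
#' fluorescence change is amplification, so any plateau-level variation
#' propagates into it.
#'
#' @param curve baseline-subtracted fluorescence per cycle.
#' @param fit an \linkS4class{FPKEstimate} from [fitBilinearToCurve()].
#' @param floor noise floor (FU).
#' @param window number of early analysed cycles averaged (default 5).
#' @return The fit with \code{i0fHat} filled in.
#' @export
estimateInitialSignal <- function(curve, fit, floor = 17.5, window = 5L) {
  stopifnot(is(fit, "FPKEstimate"))
  C <- length(curve)
  ## model efficiency of every cycle, evaluated at the observed previous
  ## fluorescence (clamped at 0: camera noise can dip below zero)
  fPrev <- pmax(c(0, curve[-C]), 0)
  eHat <- efficiencyAt(fPrev, fit@params)
  cumE <- cumprod(eHat)
  usable <- which(curve > floor)
  if (!length(usable)) stop("no cycles above the noise floor")
  win <- usable[seq_len(min(window, length(usable)))]
  fit@i0fHat <- mean(curve[win] / cumE[win])
  fit
}
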