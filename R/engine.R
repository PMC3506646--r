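## Cycle-sequential reaction engine.
##
## One cycle applies, in order: (1) previous-cycle amplicon fluorescence,
## (2) the efficiency the model assigns to that fluorescence (first-phase
## quadratic before the switch, full bilinear with the realised fc after
## it), optionally perturbed by per-cycle error, (3) amplification capped
## by the remaining primers, (4) the primer ledger update (one primer per
## new amplicon plus the side-reaction loss), (5) the phase-switch test:
## once no more than 10 percent of the initial primers remain, the
## second-phase branch governs all subsequent efficiencies and fc is fixed
## at that cycle's fluorescence.

#' Simulate one reaction
#'
#' Runs the cycle-sequential engine for a single repeat.  Amplicon
#' fluorescence is \code{fAmp * copies} by construction on every cycle,
#' which makes the fluorescence chain identical to the product form
#' \eqn{F_n = f N_0 \prod_c E_c}.  The primer ledger is exact: on every
#' cycle the primers spent equal the new amplicons made plus the
#' side-reaction loss, and the amplification increment is capped so the
#' primer count never goes negative (after exhaustion the efficiency is
#' forced to 1).
#'
#' @param cond a \linkS4class{ReactionConditions} object.
#' @param var a \linkS4class{VariationConfig} object.
#' @param draw optionally a pre-made \linkS4class{RepeatDraw}; drawn from
#'   \code{(cond, var)} when \code{NULL}.
#' @param coef link coefficients used when drawing.
#' @return A \linkS4class{ReactionTrace}.
#' @examples
#' tr <- simulateReaction(reactionConditions(50000, emax = 1.9),
#'                        noVariation())
#' switchCycle(tr)
#' @export
simulateReaction <- function(cond, var = noVariation(), draw = NULL,
                             coef = linkCoefficients()) {
  stopifnot(is(cond, "ReactionConditions"), is(var, "VariationConfig"))
  if (is.null(draw))
    draw <- drawRepeatParameters(cond, var, coef)
  stopifnot(is(draw, "RepeatDraw"))

  C <- cond@cycles
  p0 <- initialPrimerCount(cond) * draw@primerFactor
  perCycleErr <- "En" %in% var@sources && var@sigmaERel > 0

  copies <- numeric(C + 1L); primers <- numeric(C + 1L)
  eff <- numeric(C)
  copies[1L] <- draw@n0
  primers[1L] <- p0
  switched <- FALSE
  switchCycle <- NA_integer_
  fcRealized <- NA_real_
  par <- draw@params  # fc NA: single-phase branch

  for (n in seq_len(C)) {
    fPrev <- cond@fAmp * copies[n]
    y <- if (switched) ln2Efficiency(fPrev, par) else singlePhaseLn2(fPrev, par)
    e <- min(max(exp(exp(y)), 1 + 1e-12), 2)
    if (perCycleErr) {
      e <- 1 + (e - 1) * (1 + rnorm(1L, 0, var@sigmaERel))
      e <- min(max(e, 1 + 1e-12), 2)
    }
    dCopies <- copies[n] * (e - 1)
    if (dCopies > primers[n]) dCopies <- primers[n]  # exhaustion cap
    copies[n + 1L] <- copies[n] + dCopies
    sideLoss <- if (draw@gI > 0) (draw@gI / 100) * primers[n] else 0
    sideLoss <- min(sideLoss, primers[n] - dCopies)
    primers[n + 1L] <- primers[n] - dCopies - sideLoss
    eff[n] <- if (copies[n] > 0) copies[n + 1L] / copies[n] else 1
    if (!switched && primers[n + 1L] <= 0.1 * p0) {
      switched <- TRUE
      switchCycle <- n
      fcRealized <- cond@fAmp * copies[n + 1L]
      par@fc <- fcRealized
    }
  }

  fAmpFluor <- cond@fAmp * copies
  trace <- new("ReactionTrace", copies = copies, eff = eff,
               primers = primers, fAmpFluor = fAmpFluor,
               observed = fAmpFluor[-1L], switchCycle = switchCycle,
               fcRealized = fcRealized, p0 = p0, draw = draw)
  addObservationLayer(trace, var)
}

#' Add the observation layer to a trace
#'
#' The observed fluorescence of cycle n is the amplicon fluorescence plus
#' the repeat's linear baseline (intercept + slope * n, when the baseline
#' is on) plus additive camera noise (when camera noise is on).  The
#' baseline is an independent parallel process: it never feeds back into
#' the kinetics.
#'
#' @param trace a \linkS4class{ReactionTrace}.
#' @param var a \linkS4class{VariationConfig}; only the \code{baseline}
#'   and \code{camera} switches and \code{cameraSd} are used.
#' @return The trace with its \code{observed} slot replaced.
#' @export
addObservationLayer <- function(trace, var) {
  stopifnot(is(trace, "ReactionTrace"), is(var, "VariationConfig"))
  C <- length(trace@eff)
  obs <- trace@fAmpFluor[-1L]
  if (var@baseline)
    obs <- obs + trace@draw@baselineIntercept +
      trace@draw@baselineSlope * seq_len(C)
  if (var@camera && var@cameraSd > 0)
    obs <- obs + rnorm(C, 0, var@cameraSd)
  trace@observed <- obs
  trace
}

#' Simulate a plate of technical repeats
#'
#' Runs \code{nReps} independent repeats of the same reaction setup and
#' collects them in a \linkS4class{SummarizedExperiment}-based container:
#' assays \code{fluor} (observed), \code{amp} (amplicon fluorescence,
#' i.e. the baseline-free truth), \code{eff}, \code{copies} and
#' \code{primers}, all cycles x wells, with the realised per-repeat draws
#' in \code{colData}.
#'
#' @param cond a \linkS4class{ReactionConditions} object.
#' @param var a \linkS4class{VariationConfig} object.
#' @param nReps number of technical repeats (wells).
#' @param seed optional integer; when given, the global RNG is seeded so
#'   the plate regenerates bit-identically.
#' @param coef link coefficients.
#' @return A \code{SummarizedExperiment}; wells are named W001, W002, ...
#' @examples
#' pl <- simulatePlate(reactionConditions(1000, emax = 1.9),
#'                     variationConfig(), nReps = 4, seed = 7)
#' SummarizedExperiment::assayNames(pl)
#' @export
simulatePlate <- function(cond, var = variationConfig(), nReps = 100,
                          seed = NULL, coef = linkCoefficients()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nReps >= 1)
  C <- cond@cycles
  traces <- vector("list", nReps)
  for (i in seq_len(nReps))
    traces[[i]] <- simulateReaction(cond, var, coef = coef)
  wells <- sprintf("W%03d", seq_len(nReps))
  grab <- function(f) {
    m <- vapply(traces, f, numeric(C))
    dimnames(m) <- list(NULL, wells)
    m
  }
  fluor <- grab(function(t) t@observed)
  amp <- grab(function(t) t@fAmpFluor[-1L])
  effm <- grab(function(t) t@eff)
  copiesm <- grab(function(t) t@copies[-1L])
  primersm <- grab(function(t) t@primers[-1L])
  cd <- S4Vectors::DataFrame(
    well = wells,
    n0 = vapply(traces, function(t) t@draw@n0, 0),
    emaxI = vapply(traces, function(t) t@draw@emaxI, 0),
    gI = vapply(traces, function(t) t@draw@gI, 0),
    baselineIntercept = vapply(traces, function(t) t@draw@baselineIntercept, 0),
    baselineSlope = vapply(traces, function(t) t@draw@baselineSlope, 0),
    primerFactor = vapply(traces, function(t) t@draw@primerFactor, 0),
    switchCycle = vapply(traces, function(t) t@switchCycle, NA_integer_),
    fcRealized = vapply(traces, function(t) t@fcRealized, NA_real_),
    row.names = wells)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluor = fluor, amp = amp, eff = effm, copies = copiesm,
                  primers = primersm),
    rowData = S4Vectors::DataFrame(cycle = seq_len(C)),
    colData = cd)
  S4Vectors::metadata(se) <- list(
    conditions = cond, variation = var, coef = coef, seed = seed,
    p0 = initialPrimerCount(cond))
  se
}

#' Baseline-subtracted observed fluorescence of a simulated plate
#'
#' For simulated plates the generated baseline is known, so subtraction
#' is exact ("oracle subtraction"): observed minus the per-well
#' \code{intercept + slope * cycle}.  Camera noise, if any, remains.
#'
#' @param plate a plate from [simulatePlate()] (or [readPlate()], in
#'   which case per-well baseline metadata must be present).
#' @return A cycles x wells matrix.
#' @export
baselineSubtract <- function(plate) {
  fl <- SummarizedExperiment::assay(plate, "fluor")
  cd <- SummarizedExperiment::colData(plate)
  if (!all(c("baselineIntercept", "baselineSlope") %in% colnames(cd)))
    stop("plate carries no baseline metadata; subtract a fitted baseline instead")
  n <- seq_len(nrow(fl))
  bl <- outer(n, cd$baselineSlope) +
    matrix(cd$baselineIntercept, nrow(fl), ncol(fl), byrow = TRUE)
  fl - bl
}
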