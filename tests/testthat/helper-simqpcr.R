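## shared helpers: explicit-parameter draws and noise-free runs

makeDraw <- function(n0, emax, b1 = NULL, b2 = NULL,
                     coef = linkCoefficients(), g = 0) {
  if (is.null(b1)) b1 <- deriveFirstPhaseSlope(emax, coef)
  if (is.null(b2)) b2 <- deriveCurvature(b1, coef)
  p <- bilinearParams(beta1 = b1, beta2 = b2, beta3 = coef$beta3Const,
                      c = log(log(emax)), eta = coef$etaConst)
  new("RepeatDraw", n0 = n0, emaxI = emax, gI = g, baselineIntercept = 0,
      baselineSlope = 0, primerFactor = 1, params = p)
}

quietRun <- function(n0, emax, primerX = 1, cycles = 60, g = 0) {
  cond <- reactionConditions(n0, emax = emax, cycles = cycles,
                             primerConc = 260 * primerX)
  simulateReaction(cond, noVariation(), draw = makeDraw(n0, emax, g = g))
}
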