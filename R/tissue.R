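#' Forward one-compartment tissue curve
#'
#' Solves the single-compartment tissue model with extraction fraction
#' \deqn{\frac{dC_t}{dt} = k_{in}\,c_a(t) - \frac{k_{in}}{v_d}\,C_t(t),
#'   \qquad C_t(0) = 0,}
#' where \eqn{c_a} is the baseline-subtracted AIF enhancement,
#' \eqn{k_{in} = E\,F\,\rho/60} (per second, per mL tissue) and
#' \eqn{v_d = V_d\,\rho} (mL/mL). The returned tissue attenuation curve is
#' \code{baselineHu + C_t(t)} on the AIF's own grid. The integrator treats
#' the AIF as piecewise linear between grid points and advances the
#' compartment with the exact exponential update, so it is exact for
#' piecewise-linear inputs; the grid must be dense (steps no larger than
#' \code{maxStep}) rather than silently interpolated.
#'
#' @param aif a dense [ContrastCurve-class]; its pre-injection samples define
#'   the AIF baseline that is subtracted.
#' @param kinetics a [TissueKinetics-class].
#' @param baselineHu pre-contrast tissue attenuation (HU).
#' @param maxStep largest admissible AIF grid step (s); coarser grids error.
#' @return A [ContrastCurve-class] (the TAC) on the AIF grid.
#' @examples
#' aif <- generateAif(aifParameters())
#' tac <- tissueCurve(aif, tissueKinetics(flowF = 2))
#' @export
tissueCurve <- function(aif, kinetics, baselineHu = 40, maxStep = 0.011) {
  stopifnot(is(aif, "ContrastCurve"), is(kinetics, "TissueKinetics"))
  validObject(kinetics)
  t <- aif@times
  dt <- diff(t)
  stopInvalid(max(dt) > maxStep, sprintf(
    "AIF grid too coarse for the internal integrator (max step %.4g s > %.4g s)",
    max(dt), maxStep))
  pre <- t < aif@injectionStart
  aifBase <- if (any(pre)) mean(aif@values[pre]) else aif@values[1]
  ca <- aif@values - aifBase

  kin <- kinetics@extractionE * kinetics@flowF * kinetics@tissueDensity / 60
  vd <- kinetics@distVolume * kinetics@tissueDensity
  lambda <- kin / vd

  ct <- c(0, compartmentSteps(ca, dt, kin, lambda))
  contrastCurve(t, baselineHu + ct, aif@injectionStart)
}

# Exact exponential-integrator steps for dC/dt = kin*ca(t) - lambda*C with
# ca piecewise linear on the grid; vectorized through the linear recursion
# C_{n+1} = phi_n C_n + u_n (stats::filter when the grid is uniform).
compartmentSteps <- function(ca, dt, kin, lambda) {
  n <- length(dt)
  a <- ca[seq_len(n)]
  b <- (ca[-1] - a) / dt
  x <- lambda * dt
  small <- x < 1e-8
  phi <- exp(-x)
  # e1 = (1 - exp(-lambda dt)) / lambda, with series fallback near lambda = 0
  e1 <- ifelse(small, dt * (1 - x / 2 + x^2 / 6), (1 - phi) / lambda)
  # integral of exp(-lambda (dt - s)) * s ds = (dt - e1)/lambda
  e2 <- ifelse(small, dt^2 * (0.5 - x / 6 + x^2 / 24),
               (dt - e1) / lambda)
  u <- kin * (a * e1 + b * e2)
  if (all(abs(dt - dt[1]) < 1e-12)) {
    as.numeric(stats::filter(u, phi[1], method = "recursive"))
  } else {
    out <- numeric(n)
    acc <- 0
    for (i in seq_len(n)) {
      acc <- phi[i] * acc + u[i]
      out[i] <- acc
    }
    out
  }
}

#' Add Gaussian measurement noise to a curve
#'
#' Independent zero-mean Gaussian perturbation of each sample, emulating CT
#' image noise at low tube voltage. Reproducible for a given seed; the
#' session RNG state is left untouched.
#'
#' @param curve a [ContrastCurve-class] or [SampledCurve-class].
#' @param sigmaHu noise standard deviation (HU, >= 0).
#' @param seed integer seed; NULL uses (and advances) the session RNG.
#' @return A curve of the same class with perturbed values.
#' @examples
#' cc <- contrastCurve(0:59, rep(40, 60), 5)
#' identical(curveValues(addNoise(cc, 5, seed = 1)),
#'           curveValues(addNoise(cc, 5, seed = 1)))
#' @export
addNoise <- function(curve, sigmaHu, seed = NULL) {
  stopifnot(is(curve, "ContrastCurve"))
  stopInvalid(length(sigmaHu) != 1L || !is.finite(sigmaHu) || sigmaHu < 0,
              "'sigmaHu' must be a single non-negative number")
  if (sigmaHu == 0) return(curve)
  eps <- withSeed(seed, rnorm(length(curve@values), 0, sigmaHu))
  out <- curve
  out@values <- curve@values + eps
  out
}
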