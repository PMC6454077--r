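#' Generate a gamma-variate arterial input function
#'
#' Evaluates the normalized gamma-variate enhancement model on a time grid:
#' the curve sits at \code{baselineHu} until contrast arrives at
#' \code{injectionStart + tArrival}, then rises as
#' \deqn{A\,\big(\tau/(\alpha\beta)\big)^{\alpha}\exp(\alpha - \tau/\beta)}
#' with \eqn{\tau} the time since arrival. The normalization guarantees the
#' maximum enhancement equals \code{peakEnhancement} exactly, attained
#' \eqn{\alpha\beta} seconds after arrival. Recirculation is not modeled
#' (the emulated rig used a 20 L reservoir that suppresses it).
#'
#' @param params an [AifParameters-class].
#' @param times strictly increasing time grid (s). Default: a 60 s scan on a
#'   10 ms grid, matching the internal simulation resolution.
#' @param injectionStart injection onset (s); default 5 (the scan starts 5 s
#'   before the injection).
#' @return A [ContrastCurve-class] on \code{times}.
#' @examples
#' aif <- generateAif(aifParameters())
#' max(curveValues(aif)) - 40  # 250 HU peak enhancement
#' @export
generateAif <- function(params, times = seq(0, 60, by = 0.01),
                        injectionStart = 5) {
  stopifnot(is(params, "AifParameters"))
  validObject(params)
  times <- as.numeric(times)
  stopInvalid(length(times) < 2L || any(!is.finite(times)),
              "'times' must be a finite grid with at least 2 points")
  stopInvalid(any(diff(times) <= 0), "'times' must be strictly increasing")
  stopInvalid(injectionStart < 0, "'injectionStart' must be >= 0")
  t0 <- injectionStart + params@tArrival
  tau <- pmax(times - t0, 0)
  enh <- gammaVariate(tau, params@alpha, params@beta, params@peakEnhancement)
  contrastCurve(times, params@baselineHu + enh, injectionStart)
}

# Normalized gamma variate: peak value A at tau = alpha*beta, 0 at tau <= 0.
gammaVariate <- function(tau, alpha, beta, A) {
  enh <- numeric(length(tau))
  pos <- tau > 0
  # computed on the log scale to stay finite for large alpha
  enh[pos] <- A * exp(alpha * (log(tau[pos]) - log(alpha * beta)) +
                        alpha - tau[pos] / beta)
  enh
}
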