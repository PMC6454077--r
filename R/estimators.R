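#' Pre-injection baseline of a curve
#'
#' Mean of all samples acquired strictly before \code{baselineWindowEnd};
#' the scan leads the contrast injection, so these samples carry no
#' enhancement.
#'
#' @param curve a [ContrastCurve-class] or [SampledCurve-class].
#' @param cfg an [UpslopeConfig-class].
#' @return Baseline attenuation (HU).
#' @examples
#' baselineValue(contrastCurve(0:59, rep(40, 60), 5), upslopeConfig())
#' @export
baselineValue <- function(curve, cfg = upslopeConfig()) {
  stopifnot(is(curve, "ContrastCurve"), is(cfg, "UpslopeConfig"))
  pre <- curve@times < cfg@baselineWindowEnd
  if (!any(pre))
    stop("no pre-injection samples before baselineWindowEnd = ",
         cfg@baselineWindowEnd, " s; cannot estimate the baseline",
         call. = FALSE)
  mean(curve@values[pre])
}

# Rolling least-squares slope over every window of `w` consecutive samples;
# O(n) via cumulative sums, valid for irregular time grids.
rollingSlopes <- function(t, y, w) {
  n <- length(t)
  if (n < w) return(numeric(0))
  cs <- function(z) { c0 <- cumsum(z); c0[(w):n] - c(0, c0)[1:(n - w + 1)] }
  st <- cs(t); sy <- cs(y); sty <- cs(t * y); stt <- cs(t * t)
  num <- sty - st * sy / w
  den <- stt - st * st / w
  num / den
}

# Moving-average smoothing (centered, width k); edges keep partial windows.
movingAverage <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  cy <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cy[hi + 1L] - cy[lo]) / (hi - lo + 1L)
}

# Fit a smoothing spline to (t, y); returns NULL when too few points.
# Flexibility follows df = sqrt(n): it grows with sampling density (denser
# curves resolve sharper features) but sublinearly, so each basis function
# keeps averaging over several samples and per-sample noise cannot dominate
# the fitted derivative. Per-curve GCV is not used: on the few dozen samples
# an ECG-triggered scan yields it is unstable, oscillating between
# near-interpolation (noise-dominated derivatives) and gross oversmoothing.
curveSpline <- function(t, y) {
  n <- length(unique(t))
  if (n < 8L) return(NULL)
  if (var(y) < .Machine$double.eps) return(NULL)  # constant curve
  tryCatch(smooth.spline(t, y, df = min(max(4, sqrt(n)), n - 2),
                         keep.data = FALSE),
           error = function(e) NULL)
}

#' Maximum upslope of a curve
#'
#' The maximum rate of rise of a time-attenuation curve in HU/s, the
#' numerator of the maximum-upslope perfusion model. With
#' \code{smoothing = "none"} or \code{"ma"} this is the maximum over all
#' windows of \code{slopeWindow} consecutive samples of the least-squares
#' slope of value against time (after optional moving-average smoothing);
#' with \code{slopeWindow = 2} that reduces to the maximum forward finite
#' difference. With the default \code{smoothing = "spline"} a smoothing
#' spline is fitted through the samples and the maximum derivative of the
#' fitted curve is returned, emulating perfusion software that fits a curve
#' through the measured points before differentiating; when a curve has too
#' few points to support a spline fit the windowed estimate is used.
#'
#' @param curve a [ContrastCurve-class] or [SampledCurve-class].
#' @param cfg an [UpslopeConfig-class].
#' @return Maximum upslope (HU/s); can be negative for decaying curves.
#' @examples
#' ramp <- contrastCurve(0:59, 40 + 10 * (0:59), 5)
#' maxUpslope(ramp, upslopeConfig(smoothing = "none"))  # 10 HU/s
#' @export
maxUpslope <- function(curve, cfg = upslopeConfig()) {
  stopifnot(is(curve, "ContrastCurve"), is(cfg, "UpslopeConfig"))
  validObject(cfg)
  t <- curve@times
  y <- curve@values
  if (cfg@smoothing == "spline") {
    fit <- curveSpline(t, y)
    if (!is.null(fit)) {
      grid <- seq(t[1], t[length(t)], length.out = max(4L * length(t), 512L))
      return(max(predict(fit, grid, deriv = 1)$y))
    }
  }
  if (cfg@smoothing == "ma") y <- movingAverage(y, cfg@maWidth)
  stopInvalid(length(t) < cfg@slopeWindow, sprintf(
    "curve has %d samples but slopeWindow = %d", length(t), cfg@slopeWindow))
  max(rollingSlopes(t, y, as.integer(cfg@slopeWindow)))
}

#' Peak enhancement of an arterial input curve
#'
#' Maximum value above the pre-injection baseline, floored at zero: the
#' denominator of the maximum-upslope model. Under \code{smoothing =
#' "spline"} the maximum of the fitted curve is used (falling back to the
#' raw sample maximum for very short curves); \code{"ma"} takes the maximum
#' of the moving-averaged samples; \code{"none"} the raw sample maximum.
#'
#' @param curve a [ContrastCurve-class] or [SampledCurve-class].
#' @param cfg an [UpslopeConfig-class].
#' @return Peak enhancement above baseline (HU, >= 0).
#' @examples
#' aif <- generateAif(aifParameters())
#' peakEnhancement(aif, upslopeConfig())  # ~250
#' @export
peakEnhancement <- function(curve, cfg = upslopeConfig()) {
  stopifnot(is(curve, "ContrastCurve"), is(cfg, "UpslopeConfig"))
  base <- baselineValue(curve, cfg)
  y <- curve@values
  peak <- if (cfg@smoothing == "spline") {
    fit <- curveSpline(curve@times, y)
    if (is.null(fit)) max(y) else {
      grid <- seq(curve@times[1], curve@times[length(curve@times)],
                  length.out = max(4L * length(y), 512L))
      max(predict(fit, grid)$y)
    }
  } else if (cfg@smoothing == "ma") {
    max(movingAverage(y, cfg@maWidth))
  } else max(y)
  max(peak - base, 0)
}

#' Maximum-upslope MBF estimate
#'
#' The maximum-upslope perfusion model:
#' \deqn{MBF = \frac{\mathrm{MaxSlope(TAC)}}{\mathrm{PeakEnhancement(AIF)}}}
#' converted to mL/g/min by multiplying by 60 s/min and dividing by the
#' tissue density (g/mL). A negative fitted maximum slope is floored at zero
#' with a warning.
#'
#' @param tac tissue attenuation curve ([ContrastCurve-class]).
#' @param aif arterial input curve sampled by the same scheme.
#' @param cfg an [UpslopeConfig-class].
#' @param tissueDensity tissue density (g/mL).
#' @return An [MbfEstimate-class] with method "UPSLOPE".
#' @examples
#' aif <- generateAif(aifParameters())
#' tac <- tissueCurve(aif, tissueKinetics(flowF = 2, extractionE = 1,
#'                                        distVolume = 1e6))
#' mbfValue(mbfUpslope(tac, aif))  # ~2 mL/g/min
#' @export
mbfUpslope <- function(tac, aif, cfg = upslopeConfig(),
                       tissueDensity = 1.05) {
  stopifnot(is(tac, "ContrastCurve"), is(aif, "ContrastCurve"))
  stopInvalid(tissueDensity <= 0, "'tissueDensity' must be > 0")
  peak <- peakEnhancement(aif, cfg)
  if (peak <= 0)
    stop("AIF peak enhancement is zero; the input function is unusable",
         call. = FALSE)
  slope <- maxUpslope(tac, cfg)
  if (slope < 0) {
    warning("negative maximum upslope floored at zero")
    slope <- 0
  }
  value <- 60 * slope / (peak * tissueDensity)
  new("MbfEstimate", value = value, method = "UPSLOPE", maxSlope = slope,
      aifPeak = peak, k1 = NA_real_)
}

#' True (weight-based) MBF
#'
#' Ground-truth perfusion of the ex-vivo preparation: the pump input flow
#' divided by the heart weight.
#'
#' @param object input flow in mL/min (or a [HeartPhantom-class]).
#' @param heartWeight heart weight in grams (> 0).
#' @param ... unused.
#' @return MBF in mL/g/min.
#' @examples
#' trueMbf(300, 300)   # 1
#' trueMbf(1100, 500)  # 2.2
#' @export
setMethod("trueMbf", "numeric", function(object, heartWeight, ...) {
  stopInvalid(length(object) != 1L || !is.finite(object) || object < 0,
              "input flow must be a single non-negative number")
  stopInvalid(missing(heartWeight) || length(heartWeight) != 1L ||
                !is.finite(heartWeight) || heartWeight <= 0,
              "'heartWeight' must be a single positive number")
  object / heartWeight
})
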