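#' Simulate an R-wave schedule
#'
#' Draws successive RR intervals independently and uniformly from
#' \code{[60/hrMax, 60/hrMin]} seconds; the first beat falls at a random
#' offset within one RR interval of the scan start. Reproducible per seed.
#'
#' @param scheme a [SamplingScheme-class] (heart-rate range and duration).
#' @param seed integer seed; NULL uses the session RNG.
#' @return Numeric vector of R-wave times (s) within \code{[0, duration]}.
#' @examples
#' beats <- beatSchedule(samplingScheme("NON_SHUTTLE"), seed = 1)
#' range(diff(beats))  # within [60/115, 60/107]
#' @export
beatSchedule <- function(scheme, seed = NULL) {
  stopifnot(is(scheme, "SamplingScheme"))
  validObject(scheme)
  rrMin <- 60 / scheme@heartRateRange[2]
  rrMax <- 60 / scheme@heartRateRange[1]
  withSeed(seed, {
    nMax <- ceiling(scheme@duration / rrMin) + 2L
    rr <- runif(nMax, rrMin, rrMax)
    beats <- runif(1, 0, rr[1]) + c(0, cumsum(rr[-1]))
    beats[beats <= scheme@duration]
  })
}

#' Acquisition times of a scan mode
#'
#' Converts an R-wave schedule into the times the analyzed slab is imaged.
#' ECG-triggered modes fire a fixed end-systolic delay (triggerPhase times
#' the nominal RR interval, i.e. 60 / mean heart rate) after every
#' \code{slabRevisitBeats}-th R wave: every 4th beat for SHUTTLE (scans fire
#' every other beat and alternate between two table positions, so the
#' analyzed slab is revisited every 4 beats), every beat for NON_SHUTTLE.
#' CONTINUOUS ignores the ECG and returns the regular frame grid
#' \code{0, h, 2h, ...} up to but excluding \code{duration}.
#'
#' @param scheme a [SamplingScheme-class].
#' @param beats R-wave times from [beatSchedule()] (ignored by CONTINUOUS).
#' @return Numeric vector of acquisition times (s) within
#'   \code{[0, duration]}.
#' @examples
#' s <- samplingScheme("CONTINUOUS")
#' length(acquisitionTimes(s))  # 960 frames over 60 s
#' @export
acquisitionTimes <- function(scheme, beats = NULL) {
  stopifnot(is(scheme, "SamplingScheme"))
  validObject(scheme)
  if (scheme@mode == "CONTINUOUS") {
    n <- floor(scheme@duration / scheme@frameInterval)
    return((seq_len(n) - 1) * scheme@frameInterval)
  }
  stopInvalid(is.null(beats) || length(beats) == 0L,
              "ECG-triggered modes need a non-empty beat schedule")
  rrNominal <- 60 / mean(scheme@heartRateRange)
  idx <- seq(1L, length(beats), by = scheme@slabRevisitBeats)
  times <- beats[idx] + scheme@triggerPhase * rrNominal
  times[times <= scheme@duration]
}

#' Sample a dense curve at acquisition times
#'
#' Reads a dense ground-truth curve out at the given acquisition times,
#' either as point samples (linear interpolation) or, when a rotation
#' window \code{w} is given, as the mean of the curve over
#' \code{[t - w/2, t + w/2]} (clipped to the curve's span) to emulate the
#' gantry integrating over its rotation. No extrapolation: every requested
#' time must lie within the curve's span.
#'
#' @param curve a dense [ContrastCurve-class].
#' @param times acquisition times (s), increasing, within the curve's span.
#' @param scheme optional [SamplingScheme-class] carried as provenance; when
#'   supplied a [SampledCurve-class] is returned.
#' @param rotationWindow window width in seconds, or NULL (point sampling).
#' @return A [SampledCurve-class] (or plain [ContrastCurve-class] when no
#'   scheme is given).
#' @examples
#' aif <- generateAif(aifParameters())
#' sampleCurve(aif, c(0, 10, 20, 30))
#' @export
sampleCurve <- function(curve, times, scheme = NULL, rotationWindow = NULL) {
  stopifnot(is(curve, "ContrastCurve"))
  times <- as.numeric(times)
  span <- range(curve@times)
  stopInvalid(length(times) < 2L, "need at least 2 acquisition times")
  stopInvalid(any(times < span[1] - 1e-9) || any(times > span[2] + 1e-9),
              "acquisition times outside the curve's span")
  if (is.null(rotationWindow)) {
    vals <- approx(curve@times, curve@values, xout = times)$y
  } else {
    stopInvalid(rotationWindow <= 0, "'rotationWindow' must be > 0")
    vals <- vapply(times, function(t0) {
      a <- max(t0 - rotationWindow / 2, span[1])
      b <- min(t0 + rotationWindow / 2, span[2])
      inside <- curve@times > a & curve@times < b
      xs <- c(a, curve@times[inside], b)
      ys <- approx(curve@times, curve@values, xout = xs)$y
      sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2) / (b - a)
    }, numeric(1))
  }
  if (is.null(scheme))
    contrastCurve(times, vals, curve@injectionStart)
  else
    new("SampledCurve", times = times, values = vals,
        injectionStart = curve@injectionStart, scheme = scheme)
}

#' @importFrom utils head
NULL
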