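#' ContrastCurve: a time-attenuation series
#'
#' The common currency of the pipeline: a series of CT attenuation values
#' (HU) at strictly increasing times (seconds), with the contrast injection
#' onset recorded so downstream steps know where the pre-injection baseline
#' ends. Both arterial input functions (AIF) and myocardial tissue
#' attenuation curves (TAC) are stored this way.
#'
#' @slot times numeric, seconds, non-negative and strictly increasing.
#' @slot values numeric, attenuation in HU, finite, same length as times.
#' @slot injectionStart numeric scalar, injection onset in seconds relative
#'   to acquisition start (the scan leads the injection, so samples before
#'   this time are baseline).
#'
#' @seealso [contrastCurve()], [generateAif()], [tissueCurve()]
#' @export
setClass("ContrastCurve",
  representation(times = "numeric", values = "numeric",
                 injectionStart = "numeric"),
  prototype(times = c(0, 1), values = c(0, 0), injectionStart = 0))

setValidity("ContrastCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 2L)
    msg <- c(msg, "a curve needs at least 2 samples")
  if (anyNA(object@times) || any(!is.finite(object@times)))
    msg <- c(msg, "times must be finite")
  if (any(object@times < 0))
    msg <- c(msg, "times must be non-negative")
  if (length(object@times) >= 2L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@injectionStart) != 1L || is.na(object@injectionStart) ||
      object@injectionStart < 0)
    msg <- c(msg, "injectionStart must be a single non-negative number")
  else if (length(object@times) >= 1L &&
           object@injectionStart >= object@times[length(object@times)])
    msg <- c(msg, "injectionStart must precede the final sample time")
  if (length(msg)) msg else TRUE
})

#' Construct a ContrastCurve
#'
#' @param times numeric vector of sample times (s), strictly increasing.
#' @param values numeric vector of attenuation values (HU).
#' @param injectionStart injection onset (s) relative to acquisition start.
#' @return A [ContrastCurve-class].
#' @examples
#' cc <- contrastCurve(0:59, rep(40, 60), injectionStart = 5)
#' curveTimes(cc)[1:3]
#' @export
contrastCurve <- function(times, values, injectionStart = 0) {
  new("ContrastCurve", times = as.numeric(times), values = as.numeric(values),
      injectionStart = as.numeric(injectionStart))
}

#' @describeIn ContrastCurve sample times (s)
#' @param x,object a ContrastCurve
#' @export
setMethod("curveTimes", "ContrastCurve", function(x) x@times)

#' @describeIn ContrastCurve attenuation values (HU)
#' @export
setMethod("curveValues", "ContrastCurve", function(x) x@values)

#' @describeIn ContrastCurve injection onset (s)
#' @export
setMethod("injectionStart", "ContrastCurve", function(x) x@injectionStart)

#' @describeIn ContrastCurve number of samples
#' @export
setMethod("length", "ContrastCurve", function(x) length(x@times))

setMethod("show", "ContrastCurve", function(object) {
  n <- length(object@times)
  cat(sprintf("%s with %d samples over [%.3g, %.3g] s\n", class(object), n,
              object@times[1], object@times[n]))
  cat(sprintf("  values: %.1f .. %.1f HU; injection at %.3g s\n",
              min(object@values), max(object@values), object@injectionStart))
})

#' AifParameters: gamma-variate arterial input model
#'
#' Parameters of the simulated arterial input function. The enhancement
#' above baseline follows the normalized gamma-variate
#' \deqn{A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'   \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right), \quad t \ge t_0,}
#' where \eqn{t_0} is injection onset plus arrival delay. The normalization
#' makes the curve peak exactly \eqn{A} HU above baseline at
#' \eqn{t_0 + \alpha\beta}.
#'
#' @slot baselineHu pre-contrast attenuation (HU).
#' @slot tArrival contrast arrival delay after injection (s).
#' @slot alpha gamma shape (dimensionless, > 0).
#' @slot beta gamma scale (s, > 0).
#' @slot peakEnhancement peak enhancement above baseline (HU, > 0).
#' @seealso [aifParameters()], [generateAif()]
#' @export
setClass("AifParameters",
  representation(baselineHu = "numeric", tArrival = "numeric",
                 alpha = "numeric", beta = "numeric",
                 peakEnhancement = "numeric"),
  prototype(baselineHu = 40, tArrival = 4, alpha = 3, beta = 2.5,
            peakEnhancement = 250))

setValidity("AifParameters", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@baselineHu)) msg <- c(msg, "baselineHu must be one finite number")
  if (!one(object@tArrival) || object@tArrival < 0)
    msg <- c(msg, "tArrival must be a single non-negative number")
  if (!one(object@alpha) || object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (!one(object@beta) || object@beta <= 0) msg <- c(msg, "beta must be > 0")
  if (!one(object@peakEnhancement) || object@peakEnhancement < 0)
    msg <- c(msg, "peakEnhancement must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct AifParameters
#'
#' Defaults emulate a 15 mL bolus injected at 3 mL/s into the perfusion
#' circuit: arrival 4 s after injection, peak 250 HU above a 40 HU baseline,
#' time-to-peak alpha*beta = 7.5 s after arrival.
#'
#' @param baselineHu pre-contrast attenuation (HU).
#' @param tArrival arrival delay after injection (s).
#' @param alpha gamma shape.
#' @param beta gamma scale (s).
#' @param peakEnhancement peak enhancement above baseline (HU).
#' @return An [AifParameters-class].
#' @examples
#' aifParameters(peakEnhancement = 300)
#' @export
aifParameters <- function(baselineHu = 40, tArrival = 4, alpha = 3,
                          beta = 2.5, peakEnhancement = 250) {
  new("AifParameters", baselineHu = baselineHu, tArrival = tArrival,
      alpha = alpha, beta = beta, peakEnhancement = peakEnhancement)
}

setMethod("show", "AifParameters", function(object) {
  cat(sprintf(paste0("AifParameters: baseline %.4g HU, arrival %.4g s, ",
                     "alpha %.4g, beta %.4g s, peak %.4g HU\n"),
              object@baselineHu, object@tArrival, object@alpha, object@beta,
              object@peakEnhancement))
})

#' TissueKinetics: one-compartment tissue model parameters
#'
#' Ground-truth kinetics of one myocardial region: perfusion F (mL/g/min),
#' first-pass extraction fraction E, distribution volume (mL/g) governing
#' washout, and tissue density (g/mL). The blood-to-tissue transfer constant
#' is K1 = E * F (mL/g/min), exposed via [k1()].
#'
#' @slot flowF perfusion F in mL/g/min (>= 0).
#' @slot extractionE extraction fraction in (0, 1].
#' @slot distVolume contrast distribution volume in mL/g (> 0).
#' @slot tissueDensity tissue density in g/mL (> 0).
#' @seealso [tissueKinetics()], [tissueCurve()]
#' @export
setClass("TissueKinetics",
  representation(flowF = "numeric", extractionE = "numeric",
                 distVolume = "numeric", tissueDensity = "numeric"),
  prototype(flowF = 1, extractionE = 0.6, distVolume = 0.3,
            tissueDensity = 1.05))

setValidity("TissueKinetics", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@flowF) || object@flowF < 0) msg <- c(msg, "flowF must be >= 0")
  if (!one(object@extractionE) || object@extractionE <= 0 ||
      object@extractionE > 1)
    msg <- c(msg, "extractionE must be in (0, 1]")
  if (!one(object@distVolume) || object@distVolume <= 0)
    msg <- c(msg, "distVolume must be > 0")
  if (!one(object@tissueDensity) || object@tissueDensity <= 0)
    msg <- c(msg, "tissueDensity must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct TissueKinetics
#'
#' @param flowF perfusion in mL/g/min.
#' @param extractionE extraction fraction in (0, 1].
#' @param distVolume distribution volume in mL/g.
#' @param tissueDensity tissue density in g/mL.
#' @return A [TissueKinetics-class].
#' @examples
#' k1(tissueKinetics(flowF = 2, extractionE = 0.6))  # 1.2
#' @export
tissueKinetics <- function(flowF = 1, extractionE = 0.6, distVolume = 0.3,
                           tissueDensity = 1.05) {
  new("TissueKinetics", flowF = flowF, extractionE = extractionE,
      distVolume = distVolume, tissueDensity = tissueDensity)
}

#' @describeIn TissueKinetics K1 = E * F in mL/g/min
#' @param object a TissueKinetics
#' @export
setMethod("k1", "TissueKinetics", function(object)
  object@extractionE * object@flowF)

setMethod("show", "TissueKinetics", function(object) {
  cat(sprintf(paste0("TissueKinetics: F %.4g mL/g/min, E %.4g, K1 %.4g ",
                     "mL/g/min, Vd %.4g mL/g, rho %.4g g/mL\n"),
              object@flowF, object@extractionE, k1(object),
              object@distVolume, object@tissueDensity))
})

#' StenosisGrade: one FFR-graded stenosis level
#'
#' An experiment factor: the FFR label, its nominal FFR value (NA for total
#' occlusion) and the multiplier the perfusion rig applies to the baseline
#' pump flow at that grade (the rig lowers input flow at tighter stenoses to
#' hold pressure constant).
#'
#' @slot label one of FFR09, FFR08, FFR07, FFR06, FFR05, OCCLUSION.
#' @slot ffrValue nominal FFR in (0, 1]; NA_real_ for OCCLUSION.
#' @slot inputFlowFactor multiplier on baseline input flow, in (0, 1].
#' @seealso [stenosisGrade()], [stenosisGrades()], [flowForGrade()]
#' @export
setClass("StenosisGrade",
  representation(label = "character", ffrValue = "numeric",
                 inputFlowFactor = "numeric"),
  prototype(label = "FFR09", ffrValue = 0.9, inputFlowFactor = 1))

#' Ordered stenosis grade labels
#' @return Character vector of the six grade labels, healthiest first.
#' @export
gradeLabels <- function()
  c("FFR09", "FFR08", "FFR07", "FFR06", "FFR05", "OCCLUSION")

setValidity("StenosisGrade", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !object@label %in% gradeLabels())
    msg <- c(msg, sprintf("label must be one of %s",
                          paste(gradeLabels(), collapse = ", ")))
  if (length(object@ffrValue) != 1L)
    msg <- c(msg, "ffrValue must be length 1")
  else if (identical(object@label, "OCCLUSION")) {
    if (!is.na(object@ffrValue))
      msg <- c(msg, "OCCLUSION has no FFR value (use NA)")
  } else if (is.na(object@ffrValue) || object@ffrValue <= 0 ||
             object@ffrValue > 1)
    msg <- c(msg, "ffrValue must be in (0, 1]")
  if (length(object@inputFlowFactor) != 1L ||
      is.na(object@inputFlowFactor) || object@inputFlowFactor <= 0 ||
      object@inputFlowFactor > 1)
    msg <- c(msg, "inputFlowFactor must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a StenosisGrade
#'
#' @param label grade label, see [gradeLabels()].
#' @param ffrValue nominal FFR; NA for OCCLUSION.
#' @param inputFlowFactor multiplier on the baseline pump flow.
#' @return A [StenosisGrade-class].
#' @export
stenosisGrade <- function(label, ffrValue, inputFlowFactor) {
  new("StenosisGrade", label = label, ffrValue = as.numeric(ffrValue),
      inputFlowFactor = as.numeric(inputFlowFactor))
}

setMethod("show", "StenosisGrade", function(object) {
  cat(sprintf("StenosisGrade %s: FFR %s, input-flow factor %.3g\n",
              object@label,
              if (is.na(object@ffrValue)) "--" else
                sprintf("%.2f", object@ffrValue),
              object@inputFlowFactor))
})

#' HeartPhantom: one synthetic heart
#'
#' Weight, baseline pump (input) flow, the AHA 16-segment labels, the
#' circumflex (Cx) territory considered ischemic, and optional per-segment
#' flow heterogeneity multipliers.
#'
#' @slot heartId identifier.
#' @slot heartWeight grams (> 0).
#' @slot inputFlow baseline pump flow, mL/min (> 0).
#' @slot segmentIds the 16 AHA segment labels.
#' @slot ischemicSegments subset of segmentIds (Cx territory).
#' @slot segmentFlowScale named per-segment multiplier (default all 1).
#' @seealso [heartPhantom()], [flowForGrade()], [ahaSegments()]
#' @export
setClass("HeartPhantom",
  representation(heartId = "character", heartWeight = "numeric",
                 inputFlow = "numeric", segmentIds = "character",
                 ischemicSegments = "character",
                 segmentFlowScale = "numeric"))

setValidity("HeartPhantom", function(object) {
  msg <- character()
  if (length(object@heartId) != 1L || !nzchar(object@heartId))
    msg <- c(msg, "heartId must be a non-empty string")
  if (length(object@heartWeight) != 1L || !is.finite(object@heartWeight) ||
      object@heartWeight <= 0)
    msg <- c(msg, "heartWeight must be > 0")
  if (length(object@inputFlow) != 1L || !is.finite(object@inputFlow) ||
      object@inputFlow <= 0)
    msg <- c(msg, "inputFlow must be > 0")
  if (length(object@segmentIds) != 16L ||
      anyDuplicated(object@segmentIds))
    msg <- c(msg, "exactly 16 distinct AHA segments are required")
  if (!all(object@ischemicSegments %in% object@segmentIds))
    msg <- c(msg, "ischemicSegments must be a subset of segmentIds")
  if (length(object@segmentFlowScale) != length(object@segmentIds) ||
      !identical(names(object@segmentFlowScale), object@segmentIds))
    msg <- c(msg, "segmentFlowScale must be named by segmentIds")
  else if (any(!is.finite(object@segmentFlowScale)) ||
           any(object@segmentFlowScale < 0))
    msg <- c(msg, "segmentFlowScale must be non-negative")
  if (length(msg)) msg else TRUE
})

#' AHA 16-segment labels
#'
#' Standard American Heart Association 16-segment left-ventricular model:
#' segments 1-6 basal, 7-12 mid, 13-16 apical.
#'
#' @return Character vector "S01".."S16".
#' @export
ahaSegments <- function() sprintf("S%02d", 1:16)

#' Default circumflex (Cx) territory
#'
#' Lateral-wall segments supplied by the circumflex artery in the 16-segment
#' model (basal/mid anterolateral and inferolateral plus apical lateral):
#' 5, 6, 11, 12, 16. These are flagged ischemic when the Cx is stenosed,
#' leaving 11 non-ischemic segments.
#'
#' @return Character vector of 5 segment labels.
#' @export
cxTerritory <- function() sprintf("S%02d", c(5, 6, 11, 12, 16))

#' Construct a HeartPhantom
#'
#' @param heartId identifier string.
#' @param heartWeight heart weight in grams.
#' @param inputFlow baseline pump flow in mL/min.
#' @param segmentIds 16 segment labels (default [ahaSegments()]).
#' @param ischemicSegments Cx territory (default [cxTerritory()]).
#' @param segmentFlowScale per-segment flow multipliers, recycled and named
#'   by segmentIds (default all 1).
#' @return A [HeartPhantom-class].
#' @examples
#' h <- heartPhantom("H1", heartWeight = 300, inputFlow = 300)
#' trueMbf(h)  # 1 mL/g/min
#' @export
heartPhantom <- function(heartId, heartWeight, inputFlow,
                         segmentIds = ahaSegments(),
                         ischemicSegments = cxTerritory(),
                         segmentFlowScale = 1) {
  scale <- rep_len(as.numeric(segmentFlowScale), length(segmentIds))
  names(scale) <- segmentIds
  new("HeartPhantom", heartId = as.character(heartId),
      heartWeight = as.numeric(heartWeight),
      inputFlow = as.numeric(inputFlow), segmentIds = segmentIds,
      ischemicSegments = ischemicSegments, segmentFlowScale = scale)
}

#' @describeIn HeartPhantom true MBF = inputFlow / heartWeight (mL/g/min)
#' @param object a HeartPhantom
#' @param ... unused
#' @export
setMethod("trueMbf", "HeartPhantom", function(object, ...)
  object@inputFlow / object@heartWeight)

setMethod("show", "HeartPhantom", function(object) {
  cat(sprintf(paste0("HeartPhantom %s: %.4g g, input flow %.4g mL/min ",
                     "(true MBF %.3g mL/g/min), %d ischemic segments\n"),
              object@heartId, object@heartWeight, object@inputFlow,
              trueMbf(object), length(object@ischemicSegments)))
})

#' SamplingScheme: timing model of one scan mode
#'
#' Describes when one scan mode acquires images of the analyzed slab:
#' ECG-triggered shuttle (two alternating table positions, so the slab is
#' revisited every 4th beat), ECG-triggered non-shuttle (every beat), or
#' continuous (fixed frame rate, no ECG).
#'
#' @slot mode "SHUTTLE", "NON_SHUTTLE" or "CONTINUOUS".
#' @slot heartRateRange bpm interval, c(low, high).
#' @slot triggerPhase end-systolic trigger delay as a fraction of the
#'   nominal RR interval, in [0, 1).
#' @slot slabRevisitBeats beats between revisits of the analyzed slab.
#' @slot frameInterval seconds between frames (CONTINUOUS only).
#' @slot rotationTime gantry rotation time (s); used only when
#'   window-averaged sampling is requested.
#' @slot duration scan duration (s).
#' @seealso [samplingScheme()], [beatSchedule()], [acquisitionTimes()]
#' @export
setClass("SamplingScheme",
  representation(mode = "character", heartRateRange = "numeric",
                 triggerPhase = "numeric", slabRevisitBeats = "numeric",
                 frameInterval = "numeric", rotationTime = "numeric",
                 duration = "numeric"))

scanModes <- function() c("SHUTTLE", "NON_SHUTTLE", "CONTINUOUS")

setValidity("SamplingScheme", function(object) {
  msg <- character()
  if (length(object@mode) != 1L || !object@mode %in% scanModes())
    msg <- c(msg, sprintf("mode must be one of %s",
                          paste(scanModes(), collapse = ", ")))
  hr <- object@heartRateRange
  if (length(hr) != 2L || any(!is.finite(hr)) || hr[1] <= 0 ||
      hr[2] >= 300 || hr[1] > hr[2])
    msg <- c(msg, "heartRateRange must be c(low, high) within (0, 300) bpm")
  if (length(object@triggerPhase) != 1L || !is.finite(object@triggerPhase) ||
      object@triggerPhase < 0 || object@triggerPhase >= 1)
    msg <- c(msg, "triggerPhase must be in [0, 1)")
  if (length(object@slabRevisitBeats) != 1L ||
      !is.finite(object@slabRevisitBeats) || object@slabRevisitBeats < 1 ||
      object@slabRevisitBeats != round(object@slabRevisitBeats))
    msg <- c(msg, "slabRevisitBeats must be an integer >= 1")
  if (length(object@frameInterval) != 1L ||
      !is.finite(object@frameInterval) || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (length(object@rotationTime) != 1L || !is.finite(object@rotationTime) ||
      object@rotationTime <= 0)
    msg <- c(msg, "rotationTime must be > 0")
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SamplingScheme
#'
#' Defaults reproduce the three study protocols on a 60 s scan at heart
#' rates 107-115 bpm with 250 ms gantry rotation: shuttle revisits the slab
#' every 4th beat (one image every 2-3 s), non-shuttle images every beat
#' (one per 0.5-1 s), continuous acquires 16 frames per second.
#'
#' @param mode "SHUTTLE", "NON_SHUTTLE" or "CONTINUOUS".
#' @param heartRateRange bpm interval.
#' @param triggerPhase end-systolic trigger fraction of the nominal RR.
#' @param slabRevisitBeats beats between slab revisits; defaults to 4 for
#'   SHUTTLE and 1 otherwise.
#' @param frameInterval frame spacing (s) for CONTINUOUS.
#' @param rotationTime gantry rotation time (s).
#' @param duration scan duration (s).
#' @return A [SamplingScheme-class].
#' @examples
#' samplingScheme("CONTINUOUS")
#' @export
samplingScheme <- function(mode = c("SHUTTLE", "NON_SHUTTLE", "CONTINUOUS"),
                           heartRateRange = c(107, 115),
                           triggerPhase = 0.35,
                           slabRevisitBeats = NULL,
                           frameInterval = 1 / 16,
                           rotationTime = 0.25,
                           duration = 60) {
  mode <- match.arg(mode)
  if (is.null(slabRevisitBeats))
    slabRevisitBeats <- if (mode == "SHUTTLE") 4 else 1
  new("SamplingScheme", mode = mode,
      heartRateRange = as.numeric(heartRateRange),
      triggerPhase = as.numeric(triggerPhase),
      slabRevisitBeats = as.numeric(slabRevisitBeats),
      frameInterval = as.numeric(frameInterval),
      rotationTime = as.numeric(rotationTime),
      duration = as.numeric(duration))
}

#' @describeIn SamplingScheme the scan mode string
#' @param object a SamplingScheme
#' @export
setMethod("scanMode", "SamplingScheme", function(object) object@mode)

setMethod("show", "SamplingScheme", function(object) {
  cat(sprintf("SamplingScheme %s: HR %g-%g bpm, duration %g s", object@mode,
              object@heartRateRange[1], object@heartRateRange[2],
              object@duration))
  if (object@mode == "CONTINUOUS")
    cat(sprintf(", frame every %.4g s\n", object@frameInterval))
  else
    cat(sprintf(", slab revisit every %g beat(s), trigger phase %.2f\n",
                object@slabRevisitBeats, object@triggerPhase))
})

#' SampledCurve: a curve as recorded by one scan mode
#'
#' A [ContrastCurve-class] whose times are the acquisition times of a
#' [SamplingScheme-class]; the scheme is carried along as provenance.
#'
#' @slot scheme the [SamplingScheme-class] that produced the samples.
#' @seealso [sampleCurve()]
#' @export
setClass("SampledCurve", contains = "ContrastCurve",
         representation(scheme = "SamplingScheme"),
         prototype(scheme = new("SamplingScheme", mode = "CONTINUOUS",
                                heartRateRange = c(107, 115),
                                triggerPhase = 0.35, slabRevisitBeats = 1,
                                frameInterval = 1 / 16, rotationTime = 0.25,
                                duration = 60)))

setValidity("SampledCurve", function(object) {
  msg <- character()
  if (any(object@times < 0) ||
      any(object@times > object@scheme@duration + 1e-9))
    msg <- c(msg, "acquisition times must lie within [0, duration]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SampledCurve the scan mode that acquired the samples
#' @param object a SampledCurve
#' @export
setMethod("scanMode", "SampledCurve", function(object) object@scheme@mode)

#' UpslopeConfig: estimation knobs of the upslope/Patlak stage
#'
#' @slot slopeWindow number of consecutive samples per local linear fit
#'   (>= 2); used when smoothing is "none" or "ma".
#' @slot baselineWindowEnd seconds; samples strictly before this time define
#'   the pre-injection baseline.
#' @slot smoothing "none" (windowed least-squares slopes on raw samples),
#'   "ma" (moving average of width maWidth, then windowed slopes), or
#'   "spline" (smoothing-spline fit; the reported upslope is the maximum
#'   derivative of the fitted curve and the AIF peak is the fitted maximum).
#' @slot maWidth moving-average width in samples (odd, >= 1).
#' @seealso [upslopeConfig()], [maxUpslope()], [mbfUpslope()]
#' @export
setClass("UpslopeConfig",
  representation(slopeWindow = "numeric", baselineWindowEnd = "numeric",
                 smoothing = "character", maWidth = "numeric"),
  prototype(slopeWindow = 3, baselineWindowEnd = 5, smoothing = "spline",
            maWidth = 1))

setValidity("UpslopeConfig", function(object) {
  msg <- character()
  if (length(object@slopeWindow) != 1L || !is.finite(object@slopeWindow) ||
      object@slopeWindow < 2 || object@slopeWindow != round(object@slopeWindow))
    msg <- c(msg, "slopeWindow must be an integer >= 2")
  if (length(object@baselineWindowEnd) != 1L ||
      !is.finite(object@baselineWindowEnd) || object@baselineWindowEnd <= 0)
    msg <- c(msg, "baselineWindowEnd must be > 0")
  if (length(object@smoothing) != 1L ||
      !object@smoothing %in% c("none", "ma", "spline"))
    msg <- c(msg, "smoothing must be one of 'none', 'ma', 'spline'")
  if (length(object@maWidth) != 1L || !is.finite(object@maWidth) ||
      object@maWidth < 1 || object@maWidth != round(object@maWidth))
    msg <- c(msg, "maWidth must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an UpslopeConfig
#'
#' @param slopeWindow samples per local linear fit (>= 2).
#' @param baselineWindowEnd baseline cutoff time (s), default 5 (the scan
#'   leads the injection by 5 s).
#' @param smoothing "spline" (default), "ma" or "none"; see
#'   [UpslopeConfig-class].
#' @param maWidth moving-average width in samples when smoothing = "ma".
#' @return An [UpslopeConfig-class].
#' @examples
#' upslopeConfig(smoothing = "none", slopeWindow = 2)
#' @export
upslopeConfig <- function(slopeWindow = 3, baselineWindowEnd = 5,
                          smoothing = c("spline", "ma", "none"),
                          maWidth = 1) {
  smoothing <- match.arg(smoothing)
  new("UpslopeConfig", slopeWindow = as.numeric(slopeWindow),
      baselineWindowEnd = as.numeric(baselineWindowEnd),
      smoothing = smoothing, maWidth = as.numeric(maWidth))
}

#' MbfEstimate: one estimated myocardial blood flow
#'
#' @slot value MBF estimate in mL/g/min (>= 0).
#' @slot method "UPSLOPE" or "PATLAK".
#' @slot maxSlope maximum TAC upslope in HU/s (UPSLOPE; NA otherwise).
#' @slot aifPeak AIF peak enhancement in HU (UPSLOPE; NA otherwise).
#' @slot k1 transfer constant in mL/g/min (PATLAK; NA otherwise).
#' @seealso [mbfUpslope()], [patlakK1()]
#' @export
setClass("MbfEstimate",
  representation(value = "numeric", method = "character",
                 maxSlope = "numeric", aifPeak = "numeric", k1 = "numeric"),
  prototype(value = 0, method = "UPSLOPE", maxSlope = NA_real_,
            aifPeak = NA_real_, k1 = NA_real_))

setValidity("MbfEstimate", function(object) {
  msg <- character()
  if (length(object@value) != 1L || is.na(object@value) || object@value < 0)
    msg <- c(msg, "value must be a single non-negative number")
  if (length(object@method) != 1L ||
      !object@method %in% c("UPSLOPE", "PATLAK"))
    msg <- c(msg, "method must be 'UPSLOPE' or 'PATLAK'")
  if (length(msg)) msg else TRUE
})

#' @describeIn MbfEstimate the estimated MBF (mL/g/min)
#' @param object an MbfEstimate
#' @export
setMethod("mbfValue", "MbfEstimate", function(object) object@value)

setMethod("show", "MbfEstimate", function(object) {
  cat(sprintf("MbfEstimate (%s): %.4g mL/g/min", object@method,
              object@value))
  if (object@method == "UPSLOPE")
    cat(sprintf("  [max slope %.4g HU/s, AIF peak %.4g HU]\n",
                object@maxSlope, object@aifPeak))
  else
    cat(sprintf("  [K1 %.4g mL/g/min]\n", object@k1))
})

#' ImagePhantomSpec: geometry of the synthetic 4D short-axis stack
#'
#' A myocardial annulus split into AHA sectors over 3 short-axis slices
#' (6 basal + 6 mid + 4 apical), plus a circular aorta-surrogate tube looped
#' through the field of view, on a square in-plane grid.
#'
#' @slot gridSize in-plane voxels per axis.
#' @slot nSlices number of short-axis slices (3: basal, mid, apical).
#' @slot voxelSize mm per voxel (isotropic in-plane).
#' @slot innerRadius,outerRadius myocardial annulus radii (mm).
#' @slot tubeCenter in-plane tube center offset from the image center (mm).
#' @slot tubeRadius tube radius (mm).
#' @slot backgroundHu background attenuation (HU).
#' @slot noiseSigma additive Gaussian image noise SD (HU).
#' @seealso [imagePhantomSpec()], [renderPhantom()]
#' @export
setClass("ImagePhantomSpec",
  representation(gridSize = "numeric", nSlices = "numeric",
                 voxelSize = "numeric", innerRadius = "numeric",
                 outerRadius = "numeric", tubeCenter = "numeric",
                 tubeRadius = "numeric", backgroundHu = "numeric",
                 noiseSigma = "numeric"),
  prototype(gridSize = 64, nSlices = 3, voxelSize = 2, innerRadius = 20,
            outerRadius = 32, tubeCenter = c(44, 44), tubeRadius = 8,
            backgroundHu = -50, noiseSigma = 0))

setValidity("ImagePhantomSpec", function(object) {
  msg <- character()
  if (object@innerRadius <= 0 || object@outerRadius <= object@innerRadius)
    msg <- c(msg, "need 0 < innerRadius < outerRadius")
  if (object@tubeRadius <= 0) msg <- c(msg, "tubeRadius must be > 0")
  if (length(object@tubeCenter) != 2L)
    msg <- c(msg, "tubeCenter must be c(x, y) in mm")
  else if (sqrt(sum(object@tubeCenter^2)) <=
           object@outerRadius + object@tubeRadius)
    msg <- c(msg, "tube must be disjoint from the myocardial annulus")
  if (object@gridSize < 8 || object@nSlices < 3)
    msg <- c(msg, "gridSize must be >= 8 and nSlices >= 3")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  half <- object@gridSize * object@voxelSize / 2
  if (any(abs(object@tubeCenter) + object@tubeRadius > half) ||
      object@outerRadius > half)
    msg <- c(msg, "geometry must fit inside the field of view")
  if (length(msg)) msg else TRUE
})

#' Construct an ImagePhantomSpec
#'
#' @param gridSize in-plane voxels per axis.
#' @param nSlices short-axis slices (3).
#' @param voxelSize mm per voxel.
#' @param innerRadius,outerRadius annulus radii (mm).
#' @param tubeCenter tube center offset (mm, length 2).
#' @param tubeRadius tube radius (mm).
#' @param backgroundHu background attenuation (HU).
#' @param noiseSigma image noise SD (HU).
#' @return An [ImagePhantomSpec-class].
#' @export
imagePhantomSpec <- function(gridSize = 64, nSlices = 3, voxelSize = 2,
                             innerRadius = 20, outerRadius = 32,
                             tubeCenter = c(44, 44), tubeRadius = 8,
                             backgroundHu = -50, noiseSigma = 0) {
  new("ImagePhantomSpec", gridSize = as.numeric(gridSize),
      nSlices = as.numeric(nSlices), voxelSize = as.numeric(voxelSize),
      innerRadius = as.numeric(innerRadius),
      outerRadius = as.numeric(outerRadius),
      tubeCenter = as.numeric(tubeCenter),
      tubeRadius = as.numeric(tubeRadius),
      backgroundHu = as.numeric(backgroundHu),
      noiseSigma = as.numeric(noiseSigma))
}
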