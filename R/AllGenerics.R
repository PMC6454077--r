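#' @import methods
NULL

#' Time points of a curve
#'
#' @param x a [ContrastCurve-class] (or subclass).
#' @return Numeric vector of times in seconds.
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))

#' Attenuation values of a curve
#'
#' @param x a [ContrastCurve-class] (or subclass).
#' @return Numeric vector of attenuation values in HU.
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))

#' Injection onset time of a curve
#'
#' @param x a [ContrastCurve-class] (or subclass).
#' @return Injection start time in seconds relative to acquisition start.
#' @export
setGeneric("injectionStart", function(x) standardGeneric("injectionStart"))

#' Blood-to-tissue transfer constant K1
#'
#' For one-compartment kinetics K1 is the product of the extraction fraction
#' E and the perfusion F, in mL/g/min.
#'
#' @param object a [TissueKinetics-class].
#' @return K1 = E * F in mL/g/min.
#' @export
setGeneric("k1", function(object) standardGeneric("k1"))

#' Scan mode of a sampling scheme or sampled curve
#'
#' @param object a [SamplingScheme-class] or [SampledCurve-class].
#' @return One of \code{"SHUTTLE"}, \code{"NON_SHUTTLE"}, \code{"CONTINUOUS"}.
#' @export
setGeneric("scanMode", function(object) standardGeneric("scanMode"))

#' True (weight-based) myocardial blood flow of a phantom heart
#'
#' @param object a [HeartPhantom-class].
#' @param ... unused.
#' @return Input flow divided by heart weight, in mL/g/min.
#' @export
setGeneric("trueMbf", function(object, ...) standardGeneric("trueMbf"))

#' Estimated MBF value
#'
#' @param object an [MbfEstimate-class].
#' @return The MBF estimate in mL/g/min.
#' @export
setGeneric("mbfValue", function(object) standardGeneric("mbfValue"))
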