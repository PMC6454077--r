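#' Default stenosis grade table
#'
#' The six FFR-graded stenosis levels of the experiment, healthiest first.
#' The perfusion rig holds pressure constant, so pump (input) flow only
#' starts dropping at FFR 0.7; the default input-flow factors are 1.0, 1.0,
#' 0.9, 0.8, 0.7, 0.7 for FFR09..OCCLUSION. Within the ischemic (Cx)
#' territory an additional multiplier equal to the FFR value applies at
#' partial grades, and 0 at total occlusion.
#'
#' @param inputFlowFactors optional numeric(6) override of the flow factors,
#'   ordered as [gradeLabels()].
#' @return Named list of [StenosisGrade-class] objects, ordered
#'   FFR09..OCCLUSION.
#' @examples
#' stenosisGrades()$FFR07
#' @export
stenosisGrades <- function(inputFlowFactors = c(1, 1, 0.9, 0.8, 0.7, 0.7)) {
  stopInvalid(length(inputFlowFactors) != 6L ||
                any(diff(inputFlowFactors) > 0),
              "inputFlowFactors must be 6 non-increasing values")
  labs <- gradeLabels()
  ffr <- c(0.9, 0.8, 0.7, 0.6, 0.5, NA_real_)
  out <- mapply(stenosisGrade, labs, ffr, inputFlowFactors,
                SIMPLIFY = FALSE)
  names(out) <- labs
  out
}

#' Ground-truth segment flow at a stenosis grade
#'
#' True perfusion (mL/g/min) of one AHA segment of a phantom heart at a
#' given stenosis grade. Non-ischemic segments receive the weight-normalized
#' pump flow reduced by the grade's input-flow factor and scaled by the
#' segment's heterogeneity multiplier. Ischemic (Cx-territory) segments are
#' additionally multiplied by the grade's FFR value at partial grades and
#' receive zero flow at total occlusion.
#'
#' @param phantom a [HeartPhantom-class].
#' @param grade a [StenosisGrade-class].
#' @param segmentId one of \code{phantom@segmentIds}.
#' @return Flow in mL/g/min.
#' @examples
#' h <- heartPhantom("H1", 300, 300)
#' flowForGrade(h, stenosisGrades()$FFR09, "S01")  # 1 mL/g/min
#' @export
flowForGrade <- function(phantom, grade, segmentId) {
  stopifnot(is(phantom, "HeartPhantom"), is(grade, "StenosisGrade"))
  stopInvalid(length(segmentId) != 1L ||
                !segmentId %in% phantom@segmentIds,
              sprintf("unknown segment '%s'", segmentId))
  base <- phantom@inputFlow * grade@inputFlowFactor / phantom@heartWeight
  f <- base * phantom@segmentFlowScale[[segmentId]]
  if (segmentId %in% phantom@ischemicSegments)
    f <- if (identical(grade@label, "OCCLUSION")) 0 else f * grade@ffrValue
  f
}

#' Default phantom hearts
#'
#' Three synthetic hearts whose pump flows sit inside the rig's 1.0-1.2
#' L/min operating range and whose weight-based true MBF spans the ~1.8-2.8
#' mL/g/min range such ex-vivo preparations show.
#'
#' @return Named list of three [HeartPhantom-class] objects.
#' @export
defaultHearts <- function() {
  list(
    H1 = heartPhantom("H1", heartWeight = 560, inputFlow = 1000),
    H2 = heartPhantom("H2", heartWeight = 430, inputFlow = 1200),
    H3 = heartPhantom("H3", heartWeight = 580, inputFlow = 1100)
  )
}
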