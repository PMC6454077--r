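#' Write a curve as CSV with a JSON metadata sidecar
#'
#' The CSV carries columns \code{time_s, value_hu}; a sidecar
#' \code{<path>.json} records the injection onset, units and (for sampled
#' curves) the scan mode, so a curve round-trips losslessly.
#'
#' @param curve a [ContrastCurve-class] or [SampledCurve-class].
#' @param path CSV output path.
#' @return Invisibly, \code{path}.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "ContrastCurve"))
  write.csv(data.frame(time_s = curve@times, value_hu = curve@values),
            path, row.names = FALSE)
  meta <- list(injection_start_s = curve@injectionStart,
               units = list(time = "s", value = "HU"))
  if (is(curve, "SampledCurve")) meta$mode <- curve@scheme@mode
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a curve written by [writeCurve()]
#'
#' Plain two-column CSVs (\code{time_s, value_hu}) from other software are
#' accepted too; without a sidecar the injection onset defaults to 0.
#'
#' @param path CSV path.
#' @return A [ContrastCurve-class].
#' @export
readCurve <- function(path) {
  df <- read.csv(path)
  stopInvalid(!all(c("time_s", "value_hu") %in% names(df)),
              "curve CSV must have columns time_s, value_hu")
  inj <- 0
  side <- paste0(path, ".json")
  if (file.exists(side))
    inj <- jsonlite::read_json(side)$injection_start_s
  contrastCurve(df$time_s, df$value_hu, inj)
}

#' Write a measurements table
#'
#' Emits exactly the columns \code{heart_id, mode, grade, segment_id,
#' ischemic, method, mbf_ml_g_min, true_flow_ml_g_min, seed}.
#'
#' @param rows data.frame from [runExperiment()].
#' @param path CSV output path.
#' @return Invisibly, \code{path}.
#' @export
writeMeasurements <- function(rows, path) {
  cols <- c("heart_id", "mode", "grade", "segment_id", "ischemic",
            "method", "mbf_ml_g_min", "true_flow_ml_g_min", "seed")
  stopInvalid(!all(cols %in% names(rows)),
              "rows is not a measurements table")
  write.csv(rows[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a measurements table written by [writeMeasurements()]
#' @param path CSV path.
#' @return data.frame of segment measurements.
#' @export
readMeasurements <- function(path) read.csv(path)
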