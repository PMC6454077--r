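#' Median/IQR summaries of segment measurements
#'
#' Groups the measurement rows and reports, per group, the number of rows,
#' the median and quartiles of estimated MBF (linear-interpolation
#' quantiles, \code{stats::quantile} type 7), and the underestimation
#' percentage \code{100 * (1 - median / mean(true flow))}. Ischemic rows are
#' excluded by default, matching the study's non-ischemic analysis.
#'
#' @param rows data.frame from [runExperiment()].
#' @param groupKeys character vector of grouping columns (subset of
#'   heart_id, mode, grade, method, segment_id).
#' @param includeIschemic keep ischemic rows too.
#' @return data.frame with one row per group: grouping keys, n, median, q1,
#'   q3, true_flow, underestimation_pct.
#' @examples
#' rows <- runExperiment(replicates = 1, seed = 1)
#' summarizeMeasurements(rows, c("mode", "method"))
#' @export
summarizeMeasurements <- function(rows, groupKeys = c("mode", "method"),
                                  includeIschemic = FALSE) {
  stopInvalid(nrow(rows) == 0L, "no measurement rows")
  stopInvalid(!all(groupKeys %in% names(rows)),
              "groupKeys must name columns of rows")
  if (!includeIschemic) rows <- rows[!rows$ischemic, , drop = FALSE]
  rows <- rows[!is.na(rows$mbf_ml_g_min), , drop = FALSE]
  stopInvalid(nrow(rows) == 0L, "no analyzable rows after filtering")
  key <- interaction(rows[groupKeys], drop = TRUE, sep = "\r")
  parts <- split(rows, key)
  out <- lapply(parts, function(p) {
    qs <- quantile(p$mbf_ml_g_min, c(0.25, 0.5, 0.75), type = 7,
                   names = FALSE)
    truef <- mean(p$true_flow_ml_g_min)
    cbind(p[1, groupKeys, drop = FALSE],
          data.frame(n = nrow(p), median = qs[2], q1 = qs[1], q3 = qs[3],
                     true_flow = truef,
                     underestimation_pct =
                       if (truef > 0) 100 * (1 - qs[2] / truef) else NA_real_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired scan-mode contrast
#'
#' Wilcoxon signed-rank test on paired per-segment MBF differences between
#' two scan modes, pairing rows by heart, grade, segment and replicate (the
#' pairing absorbs the repeated-measures structure). Zero differences are
#' dropped per the standard signed-rank convention; if every difference is
#' zero the test is degenerate and p = 1 is reported.
#'
#' @param rows data.frame from [runExperiment()].
#' @param modeA,modeB the two scan modes to compare.
#' @param method estimation method to compare (default "UPSLOPE").
#' @param includeIschemic keep ischemic rows too.
#' @return List with \code{statistic}, \code{p_value}, \code{n_pairs},
#'   \code{median_difference} (modeB minus modeA) and \code{note}.
#' @examples
#' rows <- runExperiment(replicates = 2, seed = 1)
#' modeContrast(rows, "SHUTTLE", "CONTINUOUS")$median_difference
#' @export
modeContrast <- function(rows, modeA, modeB, method = "UPSLOPE",
                         includeIschemic = FALSE) {
  stopInvalid(!all(c(modeA, modeB) %in% rows$mode),
              "both modes must be present in rows")
  if (!includeIschemic) rows <- rows[!rows$ischemic, , drop = FALSE]
  rows <- rows[rows$method == method & !is.na(rows$mbf_ml_g_min), ,
               drop = FALSE]
  keyCols <- intersect(c("heart_id", "grade", "segment_id", "replicate"),
                       names(rows))
  key <- do.call(paste, c(rows[keyCols], sep = "\r"))
  a <- rows[rows$mode == modeA, ]
  b <- rows[rows$mode == modeB, ]
  ka <- do.call(paste, c(a[keyCols], sep = "\r"))
  kb <- do.call(paste, c(b[keyCols], sep = "\r"))
  common <- intersect(ka, kb)
  stopInvalid(length(common) < 6L,
              "fewer than 6 matched pairs; increase replicates")
  d <- b$mbf_ml_g_min[match(common, kb)] -
    a$mbf_ml_g_min[match(common, ka)]
  medDiff <- median(d)
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(list(statistic = NA_real_, p_value = 1,
                n_pairs = length(d), median_difference = 0,
                note = "all paired differences are zero"))
  }
  wt <- suppressWarnings(wilcox.test(nz, mu = 0, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(d), median_difference = medDiff,
       note = sprintf("%d zero difference(s) dropped",
                      length(d) - length(nz)))
}

#' Pearson correlation between true flow and estimated MBF
#'
#' Computed per scan mode over the non-ischemic rows; the true per-segment
#' flow tracks the pump input flow across stenosis grades, so a positive r
#' reproduces the reported coupling between input flow and MBF.
#'
#' @param rows data.frame from [runExperiment()].
#' @param method estimation method (default "UPSLOPE").
#' @param includeIschemic keep ischemic rows too.
#' @return data.frame with columns mode, r, n; r is NA (with a message) when
#'   either variable is constant.
#' @examples
#' rows <- runExperiment(replicates = 1, seed = 1)
#' flowMbfCorrelation(rows)
#' @export
flowMbfCorrelation <- function(rows, method = "UPSLOPE",
                               includeIschemic = FALSE) {
  if (!includeIschemic) rows <- rows[!rows$ischemic, , drop = FALSE]
  rows <- rows[rows$method == method & !is.na(rows$mbf_ml_g_min), ,
               drop = FALSE]
  stopInvalid(length(unique(rows$true_flow_ml_g_min)) < 3L,
              "need at least 3 distinct true-flow values")
  out <- lapply(split(rows, rows$mode), function(p) {
    r <- if (var(p$true_flow_ml_g_min) == 0 || var(p$mbf_ml_g_min) == 0) {
      message("constant variable in mode ", p$mode[1],
              "; correlation undefined")
      NA_real_
    } else cor(p$true_flow_ml_g_min, p$mbf_ml_g_min)
    data.frame(mode = p$mode[1], r = r, n = nrow(p))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
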