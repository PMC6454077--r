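#' Label map of the image phantom
#'
#' Integer labels on the spatial grid: 0 background, 1..16 the AHA segments
#' (slice 1 basal = segments 1-6, slice 2 mid = 7-12, slice 3 apical =
#' 13-16 as equal angular sectors starting at the anterior RV insertion),
#' 17 the aorta-surrogate tube (present on every slice).
#'
#' @param spec an [ImagePhantomSpec-class].
#' @return Integer array \code{gridSize x gridSize x nSlices}.
#' @export
phantomLabelmap <- function(spec) {
  stopifnot(is(spec, "ImagePhantomSpec"))
  validObject(spec)
  n <- spec@gridSize
  coord <- (seq_len(n) - (n + 1) / 2) * spec@voxelSize
  xx <- matrix(coord, n, n)
  yy <- t(xx)
  r <- sqrt(xx^2 + yy^2)
  # sector angle measured clockwise from the anterior (12 o'clock) direction
  ang <- (atan2(xx, yy) %% (2 * pi))
  inTube <- sqrt((xx - spec@tubeCenter[1])^2 +
                   (yy - spec@tubeCenter[2])^2) <= spec@tubeRadius
  inMyo <- r >= spec@innerRadius & r <= spec@outerRadius

  lab <- array(0L, dim = c(n, n, spec@nSlices))
  segsPerSlice <- c(6L, 6L, 4L)
  offset <- c(0L, 6L, 12L)
  for (s in 1:3) {
    sect <- pmin(as.integer(floor(ang / (2 * pi / segsPerSlice[s]))) + 1L,
                 segsPerSlice[s])
    sl <- matrix(0L, n, n)
    sl[inMyo] <- offset[s] + sect[inMyo]
    sl[inTube] <- 17L
    lab[, , s] <- sl
  }
  if (spec@nSlices > 3) {        # extra slices carry only the tube
    for (s in 4:spec@nSlices) {
      sl <- matrix(0L, n, n)
      sl[inTube] <- 17L
      lab[, , s] <- sl
    }
  }
  lab
}

#' Render the experiment as a synthetic 4D short-axis stack
#'
#' Paints every voxel of each AHA segment with that segment's tissue curve,
#' tube voxels with the arterial input curve, and the background with a
#' constant, at the requested frame times; optional Gaussian image noise is
#' added per voxel and frame. Together with [extractSegmentTacs()] this
#' exercises the pipeline end-to-end at the image level.
#'
#' @param spec an [ImagePhantomSpec-class].
#' @param segmentCurves named list of 16 [ContrastCurve-class] objects, one
#'   per segment label in [ahaSegments()] order 1..16.
#' @param aifCurve the arterial input [ContrastCurve-class].
#' @param frameTimes frame acquisition times (s), within every curve's span.
#' @param seed noise seed (only used when \code{spec@noiseSigma > 0}).
#' @return List with \code{stack} (4D array x,y,z,t), \code{labelmap}
#'   (3D integer array) and \code{frameTimes}.
#' @examples
#' spec <- imagePhantomSpec(gridSize = 24, tubeCenter = c(18, 18),
#'                          tubeRadius = 3, innerRadius = 6, outerRadius = 10)
#' aif <- generateAif(aifParameters())
#' segs <- setNames(rep(list(aif), 16), ahaSegments())
#' ph <- renderPhantom(spec, segs, aif, frameTimes = seq(0, 59, by = 5))
#' dim(ph$stack)
#' @export
renderPhantom <- function(spec, segmentCurves, aifCurve, frameTimes,
                          seed = NULL) {
  stopifnot(is(spec, "ImagePhantomSpec"), is(aifCurve, "ContrastCurve"))
  segs <- ahaSegments()
  stopInvalid(!all(segs %in% names(segmentCurves)),
              "segmentCurves must contain one curve per AHA segment")
  lab <- phantomLabelmap(spec)
  nvox <- length(lab)
  nt <- length(frameTimes)

  # per-label value trajectories (rows: labels 0..17, cols: frames)
  traj <- matrix(spec@backgroundHu, nrow = 18L, ncol = nt)
  for (i in seq_along(segs)) {
    cc <- segmentCurves[[segs[i]]]
    stopifnot(is(cc, "ContrastCurve"))
    traj[i + 1L, ] <- approx(cc@times, cc@values, xout = frameTimes)$y
  }
  traj[18L, ] <- approx(aifCurve@times, aifCurve@values,
                        xout = frameTimes)$y
  stopInvalid(anyNA(traj), "all curves must cover the frame times")

  stack <- array(traj[as.vector(lab) + 1L, ],
                 dim = c(dim(lab), nt))
  if (spec@noiseSigma > 0)
    stack <- stack + withSeed(seed,
      array(rnorm(nvox * nt, 0, spec@noiseSigma), dim = dim(stack)))
  list(stack = stack, labelmap = lab, frameTimes = frameTimes)
}

#' Extract per-label mean curves from a 4D stack
#'
#' Spatial mean over each label's voxels at every frame: segment labels
#' yield the segment TACs, the tube label yields the AIF.
#'
#' @param stack 4D array (x, y, z, t).
#' @param labelmap 3D integer array matching the spatial axes.
#' @param frameTimes frame times (s), length matching the 4th axis.
#' @param injectionStart injection onset (s) recorded on the curves.
#' @return Named list of [ContrastCurve-class], one per non-background
#'   label ("S01".."S16" and "TUBE").
#' @export
extractSegmentTacs <- function(stack, labelmap, frameTimes,
                               injectionStart = 5) {
  stopInvalid(!identical(dim(stack)[1:3], dim(labelmap)),
              "stack and labelmap disagree on the spatial axes")
  nt <- dim(stack)[4]
  stopInvalid(length(frameTimes) != nt,
              "frameTimes must match the stack's time axis")
  labs <- sort(setdiff(unique(as.vector(labelmap)), 0L))
  flat <- matrix(stack, nrow = length(labelmap), ncol = nt)
  out <- lapply(labs, function(L) {
    sel <- as.vector(labelmap) == L
    contrastCurve(frameTimes, colMeans(flat[sel, , drop = FALSE]),
                  injectionStart)
  })
  names(out) <- ifelse(labs == 17L, "TUBE", sprintf("S%02d", labs))
  out
}

#' Write the phantom stack and label map as NIfTI
#'
#' @param phantom result of [renderPhantom()].
#' @param stackPath output path for the 4D stack (.nii / .nii.gz).
#' @param labelPath output path for the 3D integer label map.
#' @param voxelSize voxel edge length in mm.
#' @return Invisibly, the two paths.
#' @export
writePhantomNifti <- function(phantom, stackPath, labelPath,
                              voxelSize = 2) {
  RNifti::writeNifti(RNifti::asNifti(phantom$stack,
                                     pixdim = rep(voxelSize, 3)),
                     stackPath)
  RNifti::writeNifti(RNifti::asNifti(phantom$labelmap,
                                     pixdim = rep(voxelSize, 3),
                                     datatype = "int16"),
                     labelPath)
  invisible(c(stackPath, labelPath))
}
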