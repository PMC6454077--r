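smallSpec <- function(noise = 0)
  imagePhantomSpec(gridSize = 32, voxelSize = 4, innerRadius = 20,
                   outerRadius = 32, tubeCenter = c(48, 48),
                   tubeRadius = 10, noiseSigma = noise)

segmentCurveSet <- function() {
  aif <- denseAif()
  segs <- lapply(seq_len(16), function(i)
    tissueCurve(aif, tissueKinetics(flowF = 0.5 + 0.1 * i),
                baselineHu = 40))
  names(segs) <- ahaSegments()
  list(aif = aif, segs = segs)
}

test_that("labelmap carries 18 labels with static geometry", {
  lab <- phantomLabelmap(smallSpec())
  expect_identical(sort(unique(as.vector(lab))), 0:17)
  # basal slice has segments 1-6, mid 7-12, apical 13-16, tube everywhere
  expect_setequal(setdiff(unique(as.vector(lab[, , 1])), c(0L, 17L)), 1:6)
  expect_setequal(setdiff(unique(as.vector(lab[, , 2])), c(0L, 17L)), 7:12)
  expect_setequal(setdiff(unique(as.vector(lab[, , 3])), c(0L, 17L)), 13:16)
  # annulus voxel counts identical across slices (same in-plane geometry)
  nMyo <- vapply(1:3, function(s) sum(lab[, , s] %in% 1:16), integer(1))
  expect_length(unique(nMyo), 1L)
})

test_that("noise-free render/extract round-trips the input curves", {
  cs <- segmentCurveSet()
  ft <- seq(0, 59, by = 1)
  ph <- renderPhantom(smallSpec(), cs$segs, cs$aif, ft)
  expect_identical(dim(ph$stack), c(32L, 32L, 3L, 60L))
  got <- extractSegmentTacs(ph$stack, ph$labelmap, ft)
  for (i in c(1, 7, 16)) {
    want <- approx(curveTimes(cs$segs[[i]]), curveValues(cs$segs[[i]]),
                   xout = ft)$y
    expect_equal(curveValues(got[[sprintf("S%02d", i)]]), want,
                 tolerance = 1e-12)
  }
  wantAif <- approx(curveTimes(cs$aif), curveValues(cs$aif), xout = ft)$y
  expect_equal(curveValues(got$TUBE), wantAif, tolerance = 1e-12)

  # estimating on extracted curves equals estimating on the originals
  cfg <- upslopeConfig(smoothing = "none", slopeWindow = 3)
  direct <- mbfValue(mbfUpslope(sampleCurve(cs$segs[[8]], ft),
                                sampleCurve(cs$aif, ft), cfg))
  imaged <- mbfValue(mbfUpslope(got$S08, got$TUBE, cfg))
  expect_equal(imaged, direct, tolerance = 1e-9)
})

test_that("ROI averaging reduces noise as 1/sqrt(n)", {
  cs <- segmentCurveSet()
  ft <- seq(0, 59.5, by = 0.5)
  spec <- smallSpec(noise = 20)
  ph <- renderPhantom(spec, cs$segs, cs$aif, ft, seed = 21)
  clean <- renderPhantom(smallSpec(0), cs$segs, cs$aif, ft)
  got <- extractSegmentTacs(ph$stack, ph$labelmap, ft)
  ref <- extractSegmentTacs(clean$stack, clean$labelmap, ft)
  lab <- ph$labelmap
  for (i in c(2, 9)) {
    nVox <- sum(lab == i)
    resid <- curveValues(got[[sprintf("S%02d", i)]]) -
      curveValues(ref[[sprintf("S%02d", i)]])
    expect_lt(abs(sd(resid) - 20 / sqrt(nVox)) / (20 / sqrt(nVox)), 0.35)
  }
})

test_that("renderPhantom validates inputs", {
  cs <- segmentCurveSet()
  expect_error(renderPhantom(smallSpec(), cs$segs[-3], cs$aif, 0:10),
               "one curve per AHA segment")
  expect_error(
    renderPhantom(smallSpec(), cs$segs, cs$aif, frameTimes = c(0, 200)),
    "cover the frame times")
  expect_error(imagePhantomSpec(innerRadius = 30, outerRadius = 20),
               "innerRadius")
  expect_error(imagePhantomSpec(tubeCenter = c(10, 10)), "disjoint")
})

test_that("phantom stack and labelmap survive a NIfTI round trip", {
  cs <- segmentCurveSet()
  ft <- seq(0, 55, by = 5)
  ph <- renderPhantom(smallSpec(), cs$segs, cs$aif, ft)
  d <- withr::local_tempdir()
  paths <- writePhantomNifti(ph, file.path(d, "stack.nii.gz"),
                             file.path(d, "labels.nii.gz"))
  back <- RNifti::readNifti(paths[1])
  labBack <- RNifti::readNifti(paths[2])
  expect_equal(dim(back), dim(ph$stack))
  expect_equal(as.vector(labBack), as.vector(ph$labelmap))
  expect_equal(max(abs(back - ph$stack)), 0, tolerance = 1e-5)
})
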