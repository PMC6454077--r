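test_that("baseline is the mean of pre-injection samples", {
  cfg <- upslopeConfig()
  cc <- contrastCurve(0:59, rep(40, 60), 5)
  expect_equal(baselineValue(cc, cfg), 40)
  cc2 <- contrastCurve(c(0, 2, 4, 10, 20), c(38, 40, 42, 100, 200), 5)
  expect_equal(baselineValue(cc2, cfg), 40)
  late <- contrastCurve(c(6, 10, 20), c(1, 2, 3), 5)
  expect_error(baselineValue(late, cfg), "no pre-injection samples")
  # noise-free AIF carries no enhancement before arrival
  expect_equal(baselineValue(denseAif(), cfg), 40)
})

test_that("windowed max upslope is exact on affine and constant curves", {
  for (w in c(2, 3, 5)) {
    cfg <- upslopeConfig(smoothing = "none", slopeWindow = w)
    t <- seq(0, 59, by = 1)
    expect_equal(maxUpslope(contrastCurve(t, 40 + 10 * t, 5), cfg), 10,
                 tolerance = 1e-9)
    expect_equal(maxUpslope(contrastCurve(t, rep(40, 60), 5), cfg), 0)
  }
  expect_error(
    maxUpslope(contrastCurve(c(0, 1), c(0, 1), 0),
               upslopeConfig(smoothing = "none", slopeWindow = 3)),
    "slopeWindow")
})

test_that("dense noise-free upslope recovers k_in * max AIF enhancement", {
  aif <- denseAif()
  kin <- tissueKinetics(flowF = 2, extractionE = 1, distVolume = 1e9)
  tac <- tissueCurve(aif, kin, baselineHu = 40)
  trueSlope <- (1 * 2 * 1.05 / 60) * 250
  for (sm in c("none", "spline")) {
    cfg <- upslopeConfig(smoothing = sm, slopeWindow = 2)
    expect_equal(maxUpslope(tac, cfg), trueSlope, tolerance = 0.01)
  }
})

test_that("peak enhancement handles constants, dense AIFs and subsampling", {
  cfg <- upslopeConfig()
  expect_equal(peakEnhancement(contrastCurve(0:59, rep(40, 60), 5), cfg), 0)
  expect_lt(abs(peakEnhancement(denseAif(), cfg) - 250) / 250, 0.001)
  # max over a subset of samples cannot exceed the dense max
  sh <- samplingScheme("SHUTTLE")
  at <- acquisitionTimes(sh, beatSchedule(sh, seed = 4))
  sub <- sampleCurve(denseAif(), at)
  cfgRaw <- upslopeConfig(smoothing = "none")
  expect_lte(peakEnhancement(sub, cfgRaw),
             peakEnhancement(denseAif(), cfgRaw))
})

test_that("upslope MBF formula and units are exact", {
  # synthetic curves engineered to a known slope and peak
  t <- seq(0, 60, by = 0.5)
  aif <- contrastCurve(t, 40 + ifelse(t >= 9, 120, 0), 5)
  tac <- contrastCurve(t, 40 + pmin(pmax(t - 9, 0) * 2, 40), 5)
  cfg <- upslopeConfig(smoothing = "none", slopeWindow = 2)
  est <- mbfUpslope(tac, aif, cfg, tissueDensity = 1)
  expect_equal(est@maxSlope, 2)
  expect_equal(est@aifPeak, 120)
  expect_equal(mbfValue(est), 1)         # 60 * 2 / 120
  est2 <- mbfUpslope(tac, aif, cfg, tissueDensity = 1.05)
  expect_equal(mbfValue(est2), 60 * 2 / (120 * 1.05))  # 0.952...

  flat <- contrastCurve(t, rep(40, length(t)), 5)
  expect_error(mbfUpslope(tac, flat, cfg), "unusable")
})

test_that("upslope MBF is scale-equivariant", {
  aif <- denseAif()
  tac <- tissueCurve(aif, tissueKinetics(flowF = 2), baselineHu = 40)
  scale <- function(cc, k) contrastCurve(curveTimes(cc),
                                         40 + k * (curveValues(cc) - 40),
                                         injectionStart(cc))
  for (sm in c("none", "spline")) {
    cfg <- upslopeConfig(smoothing = sm)
    base <- mbfValue(mbfUpslope(tac, aif, cfg))
    both <- mbfValue(mbfUpslope(scale(tac, 3), scale(aif, 3), cfg))
    expect_equal(both, base, tolerance = 1e-6)
    tacOnly <- mbfValue(mbfUpslope(scale(tac, 3), aif, cfg))
    expect_equal(tacOnly, 3 * base, tolerance = 1e-6)
  }
})

test_that("subsampling a noise-free curve never raises the windowed upslope", {
  aif <- denseAif()
  tac <- tissueCurve(aif, tissueKinetics(flowF = 2), baselineHu = 40)
  cfg <- upslopeConfig(smoothing = "none", slopeWindow = 2)
  dense <- maxUpslope(tac, cfg)
  for (seed in 1:25) {
    mode <- c("SHUTTLE", "NON_SHUTTLE", "CONTINUOUS")[seed %% 3 + 1]
    sch <- samplingScheme(mode)
    at <- acquisitionTimes(sch, beatSchedule(sch, seed = seed))
    sub <- sampleCurve(tac, at)
    expect_lte(maxUpslope(sub, cfg), dense + 1e-9)
  }
})

test_that("ideal-limit recovery: dense sampling, E = 1, no washout, no noise", {
  aif <- denseAif()
  for (f in c(0.5, 1, 2, 4)) {
    kin <- tissueKinetics(flowF = f, extractionE = 1, distVolume = 1e9)
    tac <- tissueCurve(aif, kin, baselineHu = 40)
    est <- mbfValue(mbfUpslope(tac, aif))
    expect_lt(abs(est - f) / f, 0.02)
  }
})

test_that("slope windows 2 and 3 agree on noise-free dense curves", {
  aif <- denseAif()
  tac <- tissueCurve(aif, tissueKinetics(flowF = 2), baselineHu = 40)
  s2 <- maxUpslope(tac, upslopeConfig(smoothing = "none", slopeWindow = 2))
  s3 <- maxUpslope(tac, upslopeConfig(smoothing = "none", slopeWindow = 3))
  expect_lt(abs(s2 - s3) / s2, 0.05)
})

test_that("true MBF is flow over weight with guarded inputs", {
  expect_equal(trueMbf(300, 300), 1)
  expect_equal(trueMbf(0, 300), 0)
  expect_equal(trueMbf(1100, 500), 2.2)
  expect_error(trueMbf(300, 0), "positive")
  expect_error(trueMbf(-5, 300), "non-negative")
})
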