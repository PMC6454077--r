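test_that("ContrastCurve enforces its invariants", {
  expect_s4_class(contrastCurve(0:10, rep(1, 11), 2), "ContrastCurve")
  expect_error(contrastCurve(c(0, 0, 1), rep(1, 3)), "strictly increasing")
  expect_error(contrastCurve(0:2, c(1, NA, 3)), "finite")
  expect_error(contrastCurve(0:2, 1:2), "equal length")
  expect_error(contrastCurve(0:2, 0:2, injectionStart = 5), "precede")
  expect_error(contrastCurve(0:2, 0:2, injectionStart = -1),
               "non-negative")
})

test_that("gamma-variate AIF peaks at the configured enhancement and time", {
  aif <- denseAif()
  enh <- curveValues(aif) - 40
  # normalization: max enhancement equals the configured peak to < 0.1%
  expect_lt(abs(max(enh) - 250) / 250, 0.001)
  # default grid spans the 60 s scan started 5 s before injection
  expect_equal(range(curveTimes(aif)), c(0, 60))
  expect_identical(injectionStart(aif), 5)
  # no enhancement before contrast arrival
  expect_true(all(enh[curveTimes(aif) < 9] == 0))

  # closed-form mode at injection + arrival + alpha * beta
  p <- aifParameters(alpha = 3, beta = 2, tArrival = 4)
  cc <- generateAif(p, seq(0, 60, by = 0.001), injectionStart = 5)
  expect_equal(curveTimes(cc)[which.max(curveValues(cc))], 15,
               tolerance = 1e-6)
})

test_that("zero-amplitude AIF is constant at baseline", {
  p <- aifParameters(peakEnhancement = 0)
  cc <- generateAif(p, seq(0, 60, by = 0.5))
  expect_true(all(curveValues(cc) == 40))
})

test_that("generateAif rejects invalid inputs", {
  expect_error(generateAif(aifParameters(), times = c(3, 2, 1)),
               "strictly increasing")
  expect_error(aifParameters(alpha = -1), "alpha")
  expect_error(aifParameters(beta = 0), "beta")
})

test_that("tissue curve matches the boxcar closed form within 0.5%", {
  t <- seq(0, 40, by = 0.01)
  A <- 100
  enh <- ifelse(t >= 5 & t <= 15, A, 0)
  aif <- contrastCurve(t, 40 + enh, injectionStart = 4)
  kin <- tissueKinetics(flowF = 2, extractionE = 0.6, distVolume = 0.3)
  tac <- tissueCurve(aif, kin, baselineHu = 40)
  oracle <- boxcarTissueOracle(t, A, 5, 15, kinOf(kin), lambdaOf(kin))
  got <- curveValues(tac) - 40
  expect_lt(max(abs(got - oracle)) / max(oracle), 0.005)
})

test_that("tissue curve matches the exponential-input closed form", {
  t <- seq(0, 40, by = 0.01)
  mu <- 0.2
  enh <- ifelse(t >= 5, 150 * exp(-mu * (t - 5)), 0)
  aif <- contrastCurve(t, 40 + enh, injectionStart = 4)
  kin <- tissueKinetics(flowF = 1.5, extractionE = 0.8, distVolume = 0.25)
  tac <- tissueCurve(aif, kin, baselineHu = 40)
  oracle <- expTissueOracle(t, 150, 5, mu, kinOf(kin), lambdaOf(kin))
  got <- curveValues(tac) - 40
  expect_lt(max(abs(got - oracle)) / max(oracle), 0.005)
})

test_that("boxcar input with negligible washout gives a linear rise", {
  t <- seq(0, 30, by = 0.01)
  enh <- ifelse(t >= 5 & t <= 15, 100, 0)
  aif <- contrastCurve(t, 40 + enh, injectionStart = 4)
  kin <- tissueKinetics(flowF = 2, extractionE = 1, distVolume = 1e9)
  tac <- tissueCurve(aif, kin, baselineHu = 0)
  ct <- curveValues(tac)
  ramp <- t >= 6 & t <= 14
  slopes <- diff(ct[ramp]) / diff(t[ramp])
  expect_equal(slopes, rep(kinOf(kin) * 100, length(slopes)),
               tolerance = 1e-6)
})

test_that("zero flow yields a flat TAC and the model is linear in the input", {
  aif <- denseAif()
  flat <- tissueCurve(aif, tissueKinetics(flowF = 0), baselineHu = 40)
  expect_true(all(curveValues(flat) == 40))

  kin <- tissueKinetics(flowF = 2)
  tac1 <- tissueCurve(aif, kin, baselineHu = 0)
  aif2 <- generateAif(aifParameters(peakEnhancement = 500))
  tac2 <- tissueCurve(aif2, kin, baselineHu = 0)
  expect_equal(curveValues(tac2), 2 * curveValues(tac1), tolerance = 1e-9)
})

test_that("tissueCurve rejects coarse grids", {
  aif <- generateAif(aifParameters(), seq(0, 60, by = 0.5))
  expect_error(tissueCurve(aif, tissueKinetics()), "too coarse")
})

test_that("max TAC slope equals k_in times max AIF enhancement when E = 1", {
  aif <- denseAif()
  kin <- tissueKinetics(flowF = 2, extractionE = 1, distVolume = 1e9)
  tac <- tissueCurve(aif, kin, baselineHu = 40)
  t <- curveTimes(tac)
  maxSlope <- max(diff(curveValues(tac)) / diff(t))
  expect_equal(maxSlope, kinOf(kin) * 250, tolerance = 0.01)
})

test_that("addNoise is reproducible, exact at sigma 0 and calibrated", {
  cc <- contrastCurve(seq(0, 99.99, by = 0.01), rep(40, 10000), 5)
  expect_identical(addNoise(cc, 0, seed = 1), cc)
  n1 <- addNoise(cc, 10, seed = 7)
  n2 <- addNoise(cc, 10, seed = 7)
  expect_identical(curveValues(n1), curveValues(n2))
  expect_lt(abs(sd(curveValues(n1) - 40) - 10) / 10, 0.03)
  expect_error(addNoise(cc, -1), "non-negative")
})

test_that("grade-to-flow mapping follows the table and territory rules", {
  h <- heartPhantom("H1", heartWeight = 300, inputFlow = 300)
  g <- stenosisGrades()
  expect_equal(flowForGrade(h, g$FFR09, "S01"), 1.0)
  expect_equal(flowForGrade(h, g$FFR08, "S01"), 1.0)  # no reduction yet
  expect_equal(flowForGrade(h, g$FFR07, "S01"), 0.9)
  expect_equal(flowForGrade(h, g$OCCLUSION, "S05"), 0)   # ischemic segment
  expect_equal(flowForGrade(h, g$FFR07, "S05"), 0.9 * 0.7)
  expect_error(flowForGrade(h, g$FFR09, "S99"), "unknown segment")

  # non-increasing along the ordered grades, for every segment
  for (s in ahaSegments()) {
    f <- vapply(g, function(gr) flowForGrade(h, gr, s), numeric(1))
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("phantom hearts expose a positive weight-based true MBF", {
  for (h in defaultHearts()) {
    expect_gt(trueMbf(h), 0)
    expect_identical(trueMbf(h), h@inputFlow / h@heartWeight)
  }
  expect_error(heartPhantom("bad", -1, 300), "heartWeight")
  expect_error(heartPhantom("bad", 300, 300, ischemicSegments = "S99"),
               "subset")
})
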