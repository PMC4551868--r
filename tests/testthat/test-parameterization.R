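# Harmonic fields, landmarks, reparameterization and template resampling.

test_that("the harmonic field on a flat strip is the linear coordinate", {
  m <- generateSulcus(flatSheetSpec(resolution = 2))
  walls <- sulcushape:::endWallSets(m)
  bv <- c(setNames(rep(0, length(walls$superior)), walls$superior),
          setNames(rep(100, length(walls$inferior)), walls$inferior))
  f <- solveHarmonicField(m, bv)
  expect_lt(max(abs(f - nodeFields(m)$y_true)), 1e-8)
})

test_that("harmonic fields obey the discrete maximum principle", {
  specs <- list(sulcusSpec(meshResolution = c(3, 3), noiseSd = 0.1, seed = 5),
                sulcusSpec(length = 70, meshResolution = c(2, 3), noiseSd = 0.05))
  for (sp in specs) {
    m <- generateSulcus(sp)
    ps <- parameterize(m)
    for (f in list(xField(ps), yField(ps))) {
      expect_gte(min(f), 0)
      expect_lte(max(f), 100)
    }
  }
})

test_that("sparse solve equals a dense direct solve on a small mesh", {
  m <- generateSulcus(sulcusSpec(length = 40, depthFn = function(y)
    6 + 2 * sin(pi * y / 100)^2, meshResolution = c(3, 2), noiseSd = 0.15,
    seed = 9L))
  expect_lt(nrow(vertices(m)), 500L)
  bv <- c(setNames(rep(0, length(topRidge(m))), topRidge(m)),
          setNames(rep(100, length(bottomRidge(m))), bottomRidge(m)))
  expect_lt(max(abs(solveHarmonicField(m, bv) - denseHarmonicOracle(m, bv))),
            1e-8)
})

test_that("solver rejects empty or constant boundary data", {
  m <- squareMesh()
  expect_error(solveHarmonicField(m, numeric(0)), "empty")
  expect_error(solveHarmonicField(m, c(`1` = 5, `2` = 5)), "distinct")
})

test_that("parameterization recovers the centerline fraction on a flat sheet", {
  ps <- parameterize(generateSulcus(flatSheetSpec()))
  expect_lt(max(abs(yField(ps) - nodeFields(ps)$y_true)), 1)  # 1% of range
  expect_lt(max(abs(xField(ps) - nodeFields(ps)$x_true)), 1)
  ep <- endpoints(ps)
  expect_identical(yField(ps)[ep["superior"]], 0)
  expect_identical(yField(ps)[ep["inferior"]], 100)
})

test_that("parameterization is invariant under rigid motion and scaling", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(2.5, 3), noiseSd = 0.05))
  ps <- parameterize(m)
  mR <- transformSulcalMesh(m, rotation = randomRotation(11),
                            translation = c(12, -5, 30))
  psR <- parameterize(mR)
  expect_lt(max(abs(xField(psR) - xField(ps))), 1e-6)
  expect_lt(max(abs(yField(psR) - yField(ps))), 1e-6)
  psS <- parameterize(transformSulcalMesh(m, scale = 2.5))
  expect_lt(max(abs(yField(psS) - yField(ps))), 1e-6)
})

test_that("landmark detection finds the profile extrema with tie-breaks", {
  y <- 1:100
  lm <- detectLandmarks(makeProfileCurve(3 * sin(2 * pi * y / 100)))
  expect_true(lm$defined)
  expect_equal(lm$L1, 25)
  expect_equal(lm$L2, 75)
  # constant profile: no extremum
  expect_false(detectLandmarks(makeProfileCurve(rep(1, 100)))$defined)
  # monotone profile: no interior extremum
  expect_false(detectLandmarks(makeProfileCurve(seq(0, 5, length.out = 100)))$defined)
  # two equal maxima at y = 40 and 60: tie toward smaller y
  v <- -(abs(y - 40) * abs(y - 60)) / 100
  expect_equal(detectLandmarks(makeProfileCurve(v))$L1, 40)
})

test_that("piecewise-linear reparameterization maps knots and segments", {
  ps <- parameterize(generateSulcus(flatSheetSpec(resolution = 2)))
  ps@L1 <- 40; ps@L2 <- 70
  rp <- reparameterize(ps, 45, 72)
  expect_equal(parameterStage(rp), "reparameterized")
  mapOf <- function(y0) {
    i <- which.min(abs(yField(ps) - y0))
    yField(rp)[i]
  }
  expect_equal(mapOf(40), 45, tolerance = 1e-6)
  expect_equal(mapOf(20), 22.5, tolerance = 1e-6)   # 20 * 45/40
  expect_identical(xField(rp), xField(ps))
  # identity targets change nothing
  id <- reparameterize(ps, 40, 70)
  expect_lt(max(abs(yField(id) - yField(ps))), 1e-12)
  # round trip through swapped targets restores y
  back <- rp; back@L1 <- 45; back@L2 <- 72
  back <- reparameterize(back, 40, 70)
  expect_lt(max(abs(yField(back) - yField(ps))), 1e-9)
  expect_error(reparameterize(ps, 72, 45), "target landmarks")
})

test_that("group landmark targets are means over defined subjects", {
  lms <- list(list(L1 = 40, L2 = 70, defined = TRUE),
              list(L1 = 50, L2 = 80, defined = TRUE))
  tgt <- groupTargetLandmarks(lms)
  expect_equal(tgt$L1, 45)
  expect_equal(tgt$L2, 75)
  expect_equal(groupTargetLandmarks(lms[1])$L1, 40)
  withUndef <- c(lms, list(list(L1 = NA_real_, L2 = NA_real_, defined = FALSE)))
  expect_warning(tgt2 <- groupTargetLandmarks(withUndef), "excluded")
  expect_equal(tgt2$L1, 45)
  expect_equal(tgt2$nExcluded, 1L)
  expect_error(groupTargetLandmarks(list(list(L1 = NA, L2 = NA))), "no subject")
})

test_that("template resampling reproduces constants, identity and linears", {
  sp <- sulcusSpec(meshResolution = c(2, 3), noiseSd = 0.05, seed = 30L)
  ps <- parameterize(generateSulcus(sp))
  tmpl <- buildTemplate(sulcusSpec(meshResolution = c(2, 3), seed = 31L))
  # identity: subject as its own template
  selfT <- new("TemplateSulcus", ps, provenance = list())
  f0 <- stats::rnorm(nrow(vertices(ps)))
  got <- resampleToTemplate(ps, selfT, list(f = f0))$f
  expect_lt(max(abs(got - f0)), 1e-9)
  # constants are exact
  gotC <- resampleToTemplate(ps, tmpl, list(f = rep(3.5, nrow(vertices(ps)))))$f
  expect_lt(max(abs(gotC - 3.5)), 1e-9)
  # a field linear in y reproduces the template's y up to grid spacing
  gotY <- resampleToTemplate(ps, tmpl, list(f = yField(ps)))$f
  spacing <- 100 / (nrow(vertices(ps)) / 5)
  expect_lt(max(abs(gotY - yField(tmpl))), spacing)
})
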