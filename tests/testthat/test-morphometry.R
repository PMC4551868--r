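# Inertial plane, signed distances, profile and depth curves, global metrics.

test_that("inertial plane of a planar mesh has its normal and zero spread", {
  m <- squareMesh()  # lies in the z = 0 plane
  ip <- inertialPlane(m)
  expect_lt(abs(abs(ip@axes[3, 3]) - 1), 1e-9)
  expect_lt(ip@eigenvalues[3], 1e-12)
  expect_lt(max(abs(signedDistances(m, ip))), 1e-9)
})

test_that("inertial plane is equivariant under rotation", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(3, 4), noiseSd = 0.1))
  ip <- inertialPlane(m)
  R <- randomRotation(3)
  ipR <- inertialPlane(transformSulcalMesh(m, rotation = R, translation = c(5, 6, 7)))
  expect_lt(max(abs(ipR@eigenvalues - ip@eigenvalues)) / ip@eigenvalues[1], 1e-9)
  for (k in 1:3)
    expect_lt(abs(abs(sum((R %*% ip@axes[, k]) * ipR@axes[, k])) - 1), 1e-6)
})

test_that("a 6-point cloud matches the brute-force eigen decomposition", {
  set.seed(12)
  V <- matrix(rnorm(18, sd = 4), 6, 3)
  F <- rbind(c(1L, 2L, 3L), c(3L, 2L, 4L), c(3L, 4L, 5L), c(5L, 4L, 6L))
  m <- SulcalMesh(V, F, topRidge = c(1L, 2L), bottomRidge = c(5L, 6L),
                  endpointSuperior = 1L, endpointInferior = 2L,
                  validate = FALSE)
  ip <- inertialPlane(m)
  Vc <- sweep(V, 2, colMeans(V))
  eg <- eigen(t(Vc) %*% Vc / nrow(V))   # brute-force 3x3 covariance
  expect_equal(ip@eigenvalues, eg$values, tolerance = 1e-9)
  for (k in 1:3)
    expect_lt(abs(abs(sum(ip@axes[, k] * eg$vectors[, k])) - 1), 1e-9)
})

test_that("signed distances centre to zero and respect mirror symmetry", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(2, 3)))
  d <- signedDistances(m)
  expect_lt(abs(sum(d)), 1e-6)
  # two constructed points mirror-symmetric about the plane
  ip <- inertialPlane(m)
  p <- ip@barycenter + 2 * ip@axes[, 3] + 5 * ip@axes[, 1]
  q <- ip@barycenter - 2 * ip@axes[, 3] + 5 * ip@axes[, 1]
  dp <- sum((p - ip@barycenter) * ip@axes[, 3])
  dq <- sum((q - ip@barycenter) * ip@axes[, 3])
  expect_equal(dp, -dq, tolerance = 1e-12)
})

test_that("the profile of a flat sheet vanishes and binning is consistent", {
  ps <- parameterize(generateSulcus(flatSheetSpec()))
  pc <- profileCurve(ps)
  expect_lt(max(abs(profileValues(pc))), 1e-6)
  expect_lt(max(abs(pc@values)), max(abs(pc@nodeDistances)) + 1e-12)
  # halving P: count-weighted pair averages reproduce the coarser curve
  ps2 <- parameterize(generateSulcus(sulcusSpec(meshResolution = c(2, 3),
                                                noiseSd = 0.1, seed = 6L)))
  c100 <- profileCurve(ps2, P = 100L)
  c50 <- profileCurve(ps2, P = 50L)
  odd <- seq(1, 99, by = 2); even <- odd + 1
  w <- c100@counts[odd] + c100@counts[even]
  merged <- (c100@values[odd] * c100@counts[odd] +
             c100@values[even] * c100@counts[even]) / w
  ok <- w > 0 & c100@counts[odd] > 0 & c100@counts[even] > 0 & c50@counts > 0
  expect_lt(max(abs(merged[ok] - c50@values[ok])), 1e-9)
})

test_that("profile recovery on the generated sulcus tracks ground truth", {
  m <- generateSulcus(sulcusSpec())
  pc <- profileCurve(parameterize(m))
  gt <- groundTruth(m)
  meas <- profileValues(pc)
  expect_lt(abs(max(abs(meas)) - gt$profileAmplitude) / gt$profileAmplitude,
            0.1)
  expect_lte(abs(which.max(meas) - which.max(gt$profileCurve)), 2)
})

test_that("too coarse a mesh for the requested positions errors", {
  ps <- parameterize(generateSulcus(sulcusSpec(meshResolution = c(8, 5))))
  expect_error(profileCurve(ps, P = 100L), "empty")
})

test_that("flat-sheet depth is exact and modes agree", {
  ps <- parameterize(generateSulcus(flatSheetSpec()))
  g <- depthPositionProfile(ps, mode = "geodesic")
  e <- depthPositionProfile(ps, mode = "euclidean")
  expect_lt(max(abs(depthValues(g) - 12)), 0.12)
  expect_lt(max(abs(depthValues(e) - 12)), 0.12)
  expect_equal(unname(depthSummary(g)["averageDepth"]), 12, tolerance = 0.01)
  expect_equal(unname(depthSummary(g)["maxDepth"]), 12, tolerance = 0.01)
})

test_that("the DPP tracks a curved fundus and geodesic >= euclidean", {
  m <- generateSulcus(sulcusSpec(depthFn = function(y)
    13 + 2 * sin(2 * pi * y / 100)))
  ps <- parameterize(m)
  gt <- groundTruth(m)
  g <- depthValues(depthPositionProfile(ps))
  expect_lt(max(abs(g - gt$depthCurve) / gt$depthCurve), 0.05)
  e <- depthValues(depthPositionProfile(ps, mode = "euclidean"))
  expect_true(all(g >= e - 1e-9))
})

test_that("depth summary is the mean and max of the profile", {
  dpp <- new("DepthPositionProfile", positions = 1:3, depth = c(10, 12, 14),
             mode = "euclidean", flagged = rep(FALSE, 3))
  expect_equal(unname(depthSummary(dpp)), c(12, 14))
})

test_that("sulcal length averages the two ridge arclengths", {
  V <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 5, -2), c(98, 5, -2))
  # straight top ridge 100 mm; straight bottom ridge 98 mm
  F <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L))
  m <- SulcalMesh(V, F, topRidge = c(1L, 2L), bottomRidge = c(3L, 4L),
                  endpointSuperior = 1L, endpointInferior = 2L)
  expect_equal(sulcalLength(m), 99)
  mR <- transformSulcalMesh(m, rotation = randomRotation(2), translation = 1:3)
  expect_equal(sulcalLength(mR), 99, tolerance = 1e-9)
})

test_that("span measures parallel banks exactly and needs both banks", {
  m <- generateSulcus(flatSheetSpec(resolution = 2))
  s <- sulcalSpan(m)
  expect_lt(abs(as.numeric(s) - 2.4), 1e-6)
  expect_equal(attr(s, "validFraction"), 1)
  m2 <- m
  m2@companions$bankPosterior <- NULL
  expect_error(sulcalSpan(m2), "bank")
})

test_that("span recovers the generator parameter on a curved sulcus", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(2, 3)))
  s <- as.numeric(sulcalSpan(m, maxNodes = 250))
  expect_lt(abs(s - 2.35) / 2.35, 0.02)
})

test_that("cortical thickness works from interfaces or a field", {
  m <- generateSulcus(flatSheetSpec(resolution = 2))
  expect_lt(abs(as.numeric(corticalThickness(m, method = "interfaces")) - 3),
            1e-6)
  m2 <- m
  m2@nodeFields$thickness <- rep(3.83, nrow(vertices(m)))
  expect_equal(corticalThickness(m2, method = "field"), 3.83)
  varying <- generateSulcus(sulcusSpec(
    thicknessFn = function(y) 3 + 0.8 * sin(pi * y / 100),
    meshResolution = c(2, 3)))
  gt <- groundTruth(varying)
  expect_lt(abs(corticalThickness(varying, method = "field") - gt$thickness) /
              gt$thickness, 0.02)
  m3 <- m
  m3@companions <- list()
  m3@nodeFields$thickness <- NULL
  expect_error(corticalThickness(m3), "no thickness source")
})

test_that("surface area is exact on squares and obeys the scaling law", {
  sq <- squareMesh()
  expect_equal(surfaceArea(sq), 1)
  expect_equal(surfaceArea(transformSulcalMesh(sq, scale = 3)), 9)
})

test_that("all global metrics are rigid-invariant and scale correctly", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(2, 3), noiseSd = 0.05))
  ps <- parameterize(m)
  gm <- globalMetrics(ps, spanMaxNodes = 150)
  expect_gte(gm@maxDepth, gm@averageDepth)
  R <- randomRotation(8)
  mR <- transformSulcalMesh(m, rotation = R, translation = c(-4, 9, 2))
  gmR <- globalMetrics(parameterize(mR), spanMaxNodes = 150)
  a <- unlist(as.data.frame(gm)); b <- unlist(as.data.frame(gmR))
  expect_lt(max(abs(b - a) / abs(a)), 1e-6)
  s <- 1.7
  gmS <- globalMetrics(parameterize(transformSulcalMesh(m, scale = s)),
                       spanMaxNodes = 150)
  cS <- unlist(as.data.frame(gmS))
  lin <- c("average_length", "average_depth", "max_depth", "average_span",
           "average_thickness")
  expect_lt(max(abs(cS[lin] / a[lin] - s)), 1e-6 * s)
  expect_lt(abs(cS["surface_area"] / a["surface_area"] - s^2), 1e-6 * s^2)
})
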