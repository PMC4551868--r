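# Mesh and cohort I/O, validation, and accessory-branch pruning.

test_that("a minimal two-triangle square is a valid SulcalMesh", {
  m <- squareMesh()
  expect_s4_class(m, "SulcalMesh")
  expect_equal(nrow(vertices(m)), 4L)
  expect_equal(nrow(triangles(m)), 2L)
})

test_that("ridge paths sharing a non-endpoint vertex are rejected", {
  m <- generateSulcus(flatSheetSpec(resolution = 6))
  br <- bottomRidge(m)
  br[3] <- topRidge(m)[3]  # interior vertex shared between the two ridges
  expect_error(
    SulcalMesh(vertices(m), triangles(m), topRidge(m), br,
               endpoints(m)["superior"], endpoints(m)["inferior"]),
    "non-endpoint")
})

test_that("degenerate triangles and non-manifold meshes are rejected", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
             c(0.5, 0.5, 1), c(0.5, 0.5, -1))
  Fnm <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L), c(1L, 2L, 5L), c(2L, 1L, 6L))
  expect_error(
    SulcalMesh(V, Fnm, topRidge = c(1L, 2L), bottomRidge = c(3L, 4L),
               endpointSuperior = 1L, endpointInferior = 2L),
    "manifold")
  Vdeg <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 1, 0))
  expect_error(
    SulcalMesh(Vdeg, rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)),
               topRidge = c(1L, 2L), bottomRidge = c(3L, 4L),
               endpointSuperior = 1L, endpointInferior = 2L),
    "degenerate")
})

test_that("write-read round trip preserves geometry, labels and fields", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(4, 4), noiseSd = 0.1,
                                 seed = 3L))
  for (ext in c("off", "ply", "gii")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    writeSulcalMesh(m, path)
    m2 <- readSulcalMesh(path)
    expect_lt(max(abs(vertices(m2) - vertices(m))), 1e-6)
    expect_identical(triangles(m2), triangles(m))
    expect_identical(topRidge(m2), topRidge(m))
    expect_identical(bottomRidge(m2), bottomRidge(m))
    expect_identical(unname(endpoints(m2)), unname(endpoints(m)))
    expect_lt(max(abs(nodeFields(m2)$thickness - nodeFields(m)$thickness)),
              1e-6)
  }
})

test_that("the loader fails loudly on missing files or labels", {
  expect_error(readSulcalMesh(file.path(tempdir(), "nope.off")), "not found")
  m <- squareMesh()
  path <- file.path(tempdir(), "nolabels.off")
  writeSulcalMesh(m, path)
  file.remove(paste0(path, ".labels.json"))
  expect_error(readSulcalMesh(path), "sidecar")
})

test_that("disconnected flaps are removed, the main sheet untouched", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(4, 4)))
  n0 <- nrow(vertices(m))
  # a separate 3 mm flap far from the sheet
  flapV <- rbind(c(50, 50, 50), c(53, 50, 50), c(50, 53, 50))
  V2 <- rbind(vertices(m), flapV)
  F2 <- rbind(triangles(m), n0 + c(1L, 2L, 3L))
  dirty <- SulcalMesh(V2, matrix(as.integer(F2), ncol = 3), topRidge(m),
                      bottomRidge(m), endpoints(m)[1], endpoints(m)[2],
                      nodeFields = lapply(nodeFields(m), function(f)
                        c(f, NA, NA, NA)),
                      validate = FALSE)
  clean <- removeAccessoryBranches(dirty)
  expect_equal(nrow(vertices(clean)), n0)
  expect_equal(vertices(clean), vertices(m))
  expect_equal(triangles(clean), triangles(m))
})

test_that("attached fins are pruned by the 5 mm threshold and not beyond", {
  m <- generateSulcus(sulcusSpec(meshResolution = c(4, 4)))
  planted <- plantAccessoryFin(m, finLength = 4)
  clean <- removeAccessoryBranches(planted$mesh)
  expect_equal(nrow(triangles(clean)), nrow(triangles(m)))
  expect_equal(vertices(clean), vertices(m))
  # idempotent
  again <- removeAccessoryBranches(clean)
  expect_identical(vertices(again), vertices(clean))
  expect_identical(triangles(again), triangles(clean))
  # a 6 mm branch survives the default threshold
  big <- plantAccessoryFin(m, finLength = 6)
  kept <- removeAccessoryBranches(big$mesh)
  expect_equal(nrow(triangles(kept)), nrow(triangles(big$mesh)))
  # ... but not a lower one
  expect_equal(nrow(triangles(removeAccessoryBranches(big$mesh,
                                                      lengthThreshold = 7))),
               nrow(triangles(m)))
})

test_that("cohort tables load, validate and fail informatively", {
  tab <- simulateProfileCurves(nPerGroup = 21, seed = 8)$cohort
  path <- file.path(tempdir(), "cohort.csv")
  write.csv(tab, path, row.names = FALSE)
  got <- readCohortTable(path)
  expect_equal(nrow(got), 42L)
  expect_equal(unname(table(got$group)), c(21L, 21L), ignore_attr = TRUE)

  bad <- tab
  bad$group[1] <- "other"
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCohortTable(path), "two levels")

  bad <- tab
  bad$age_months[5] <- NA
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCohortTable(path), bad$subject_id[5])

  bad <- tab
  bad$subject_id[2] <- bad$subject_id[1]
  write.csv(bad, path, row.names = FALSE)
  expect_error(readCohortTable(path), "duplicate")

  expect_error(validateCohortTable(tab[, -3]), "lacks columns")
})
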