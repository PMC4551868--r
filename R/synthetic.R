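# Synthetic sulcal-mesh and cohort generator. The mesh is a folded ribbon
# built as a tensor-product grid over (y, depth) and triangulated, which makes
# length, area and depth ground truth available by quadrature of the defining
# functions. Defaults emulate a child central sulcus: ~98 mm long, mean depth
# 13 mm peaking at 18.25 mm, bank-to-bank span 2.35 mm, cortical thickness
# 3.23 mm, and a 3 mm sinusoidal profile undulation standing in for the hand
# knob. Internally the superior end sits at y = 0.

#' Specify a synthetic sulcus
#'
#' Returns a \linkS4class{SulcusSpec} describing one folded-ribbon sulcal
#' mesh. Defaults are modelled on control-group central-sulcus morphometry in
#' late childhood (see the package vignette for the rationale behind each
#' number).
#'
#' @param length sulcus length in mm.
#' @param depthFn function of y in [0, 100] giving the local depth (mm);
#'   must be positive.
#' @param profileFn function of y giving the lateral ribbon displacement (mm).
#' @param span bank-to-bank distance (mm).
#' @param thicknessFn function of y giving cortical thickness (mm).
#' @param meshResolution target edge length in mm; a scalar, or
#'   \code{c(along, depth)} to use different spacings along the sulcus and
#'   down the ribbon.
#' @param seed RNG seed for the vertex jitter.
#' @param noiseSd SD of the Gaussian vertex jitter (mm).
#' @return A \linkS4class{SulcusSpec}.
#' @export
sulcusSpec <- function(length = 98,
                       depthFn = function(y) 7.75 + 10.5 * sin(pi * y / 100)^2,
                       profileFn = function(y) 3 * sin(2 * pi * y / 100),
                       span = 2.35,
                       thicknessFn = function(y) rep(3.23, base::length(y)),
                       meshResolution = 1, seed = 1L, noiseSd = 0) {
  obj <- new("SulcusSpec", length = length, depthFn = depthFn,
    profileFn = profileFn, span = span, thicknessFn = thicknessFn,
    meshResolution = meshResolution, seed = as.integer(seed), noiseSd = noiseSd)
  validObject(obj)
  obj
}

#' Generate a synthetic sulcal mesh
#'
#' Builds the labeled folded-ribbon mesh described by a
#' \linkS4class{SulcusSpec}: a grid of (along-sulcus, depth) positions with
#' the centerline displaced laterally by \code{profileFn} and the fundus at
#' \code{depthFn(y)}; companion gyral banks at +/- span/2 along the medial
#' vertex normals and CSF/GM and GM/WM interfaces at +/- thickness/2; top and
#' bottom ridges and the two endpoints labeled; a \code{groundTruth} record
#' (quadrature values of length, area, depth, profile) attached to
#' \code{meshMeta()}.
#'
#' @param spec a \linkS4class{SulcusSpec}.
#' @param meta extra metadata entries (subject id, group, hemisphere...).
#' @return A validated \linkS4class{SulcalMesh}.
#' @export
generateSulcus <- function(spec, meta = list()) {
  res <- spec@meshResolution
  resY <- res[1]; resX <- if (length(res) == 2L) res[2] else res[1]
  L <- spec@length
  ny <- max(2L, as.integer(round(L / resY)))       # columns - 1
  if (ny + 1L < 10L)
    stop("mesh resolution too coarse: fewer than 10 rows along the sulcus")
  yCols <- seq(0, 100, length.out = ny + 1L)
  depthCols <- spec@depthFn(yCols)
  nx <- max(2L, as.integer(ceiling(max(depthCols) / resX)))  # rows - 1
  s <- seq(0, 1, length.out = nx + 1L)
  prof <- spec@profileFn(yCols)
  thick <- spec@thicknessFn(yCols)

  nvCol <- nx + 1L
  n <- nvCol * (ny + 1L)
  jIdx <- rep(seq_len(ny + 1L), each = nvCol)   # column of each vertex
  iIdx <- rep(seq_len(nvCol), times = ny + 1L)  # row (1 = top ridge)
  V <- cbind(prof[jIdx],
             L * yCols[jIdx] / 100,
             -s[iIdx] * depthCols[jIdx])
  if (spec@noiseSd > 0)
    V <- V + withSeed(spec@seed,
      matrix(rnorm(3L * n, sd = spec@noiseSd), n, 3))

  vid <- function(i, j) (j - 1L) * nvCol + i
  jj <- rep(seq_len(ny), each = nx)
  ii <- rep(seq_len(nx), times = ny)
  F <- rbind(cbind(vid(ii, jj), vid(ii + 1L, jj), vid(ii, jj + 1L)),
             cbind(vid(ii + 1L, jj), vid(ii + 1L, jj + 1L), vid(ii, jj + 1L)))
  F <- matrix(as.integer(F), ncol = 3)

  topRidge <- vid(1L, seq_len(ny + 1L))
  bottomRidge <- vid(nvCol, seq_len(ny + 1L))

  normals <- vertexNormals(V, F)
  offsetMesh <- function(dist) list(vertices = V + dist * normals, triangles = F)
  halfThick <- thick[jIdx] / 2
  companions <- list(
    bankAnterior = offsetMesh(spec@span / 2),
    bankPosterior = offsetMesh(-spec@span / 2),
    interfaceOuter = list(vertices = V + halfThick * normals, triangles = F),
    interfaceInner = list(vertices = V - halfThick * normals, triangles = F))

  nodeFields <- list(
    thickness = thick[jIdx],
    y_true = yCols[jIdx],
    x_true = 100 * s[iIdx],
    profile_true = prof[jIdx])

  meta$groundTruth <- sulcusGroundTruth(spec)
  mesh <- SulcalMesh(V, F, topRidge, bottomRidge,
    endpointSuperior = vid(1L, 1L), endpointInferior = vid(1L, ny + 1L),
    companions = companions, nodeFields = nodeFields, meta = meta)
  mesh
}

# Quadrature ground truth for the smooth surface a SulcusSpec describes.
# The profile truth is the signed distance of the ideal surface to its own
# (continuous) inertial plane, averaged over the ribbon at each y -- not the
# raw profileFn: whenever profileFn correlates with y (a full-period sine
# does), the inertial plane tilts and the measured profile legitimately
# carries the induced linear trend.
sulcusGroundTruth <- function(spec, P = 100L, nQuad = 2001L) {
  y <- seq(0, 100, length.out = nQuad)
  L100 <- spec@length / 100
  d <- spec@depthFn(y)
  p <- spec@profileFn(y)
  h <- y[2] - y[1]
  dp <- c(diff(p) / h, 0); dp[nQuad] <- dp[nQuad - 1L]
  dd <- c(diff(d) / h, 0); dd[nQuad] <- dd[nQuad - 1L]
  topLen <- trapzQuad(y, sqrt(L100^2 + dp^2))
  bottomLen <- trapzQuad(y, sqrt(L100^2 + dp^2 + dd^2))
  area <- trapzQuad(y, d * sqrt(L100^2 + dp^2))
  yPos <- seq_len(P) * 100 / P
  depthCurve <- spec@depthFn(yPos)
  prof <- idealProfileTruth(spec, yPos)
  list(length = mean(c(topLen, bottomLen)), topLength = topLen,
    bottomLength = bottomLen, area = area,
    positions = yPos, depthCurve = depthCurve,
    averageDepth = mean(depthCurve), maxDepth = max(depthCurve),
    profileCurve = prof,
    profileAmplitude = max(abs(prof)),
    profilePeakPosition = which.max(abs(prof)),
    span = spec@span, thickness = trapzQuad(y, spec@thicknessFn(y)) / 100)
}

# Signed-distance-to-inertial-plane truth of the ideal surface, by uniform
# (t, s) quadrature mirroring the uniform vertex weighting of the discrete
# estimator.
idealProfileTruth <- function(spec, yPos, nt = 601L, ns = 21L) {
  yq <- seq(0, 100, length.out = nt)
  s <- seq(0, 1, length.out = ns)
  prof <- spec@profileFn(yq); dep <- spec@depthFn(yq)
  X <- rep(prof, each = ns)
  Y <- rep(spec@length * yq / 100, each = ns)
  Z <- as.vector(outer(-s, dep))
  pts <- cbind(X, Y, Z)
  ctr <- colMeans(pts)
  ptsC <- sweep(pts, 2, ctr)
  eg <- eigen(crossprod(ptsC), symmetric = TRUE)
  u3 <- eg$vectors[, 3]
  # anatomical orientation: the generator's anterior bank lies toward +x
  if (u3[1] < 0) u3 <- -u3
  # mean signed distance over the ribbon at each requested y
  profY <- spec@profileFn(yPos); depY <- spec@depthFn(yPos)
  sMean <- mean(s)
  vapply(seq_along(yPos), function(i) {
    px <- profY[i] - ctr[1]
    py <- spec@length * yPos[i] / 100 - ctr[2]
    pz <- mean(-s * depY[i]) - ctr[3]
    px * u3[1] + py * u3[2] + pz * u3[3]
  }, numeric(1))
}

# Random smooth function on [0, 100] with pointwise SD `sd`, built from the
# first `nModes` cosine/sine modes. Used for between-subject shape variation.
randomSmoothFn <- function(sd, nModes = 6L) {
  if (sd <= 0) return(function(y) rep(0, length(y)))
  a <- rnorm(nModes, sd = sd / sqrt(nModes))
  b <- rnorm(nModes, sd = sd / sqrt(nModes))
  function(y) {
    out <- numeric(length(y))
    for (k in seq_len(nModes))
      out <- out + a[k] * cos(k * pi * y / 100) + b[k] * sin(k * pi * y / 100)
    out
  }
}

# Plateau window indicator with smoothstep edges (fraction `edge` of the
# window width on each side), so mesh-level window effects stay smooth.
windowBump <- function(window, edge = 0.15) {
  lo <- window[1]; hi <- window[2]
  w <- (hi - lo) * edge
  function(y) {
    r <- numeric(length(y))
    inside <- y >= lo & y <= hi
    r[inside] <- 1
    up <- inside & y < lo + w
    r[up] <- {
      tt <- (y[up] - lo) / w
      tt * tt * (3 - 2 * tt)
    }
    dn <- inside & y > hi - w
    r[dn] <- {
      tt <- (hi - y[dn]) / w
      tt * tt * (3 - 2 * tt)
    }
    r
  }
}

perGroup <- function(x, group) {
  if (length(x) == 1L) return(unname(x))
  unname(x[[group]])
}

#' Specify a synthetic two-group cohort
#'
#' Returns a \linkS4class{CohortSpec}. The defaults emulate the study
#' conditions the package is validated against: 21 subjects per group, the
#' case group deeper by 1.33 mm and thicker by 0.60 mm with a mid-section
#' profile effect, between-subject average-depth SDs of 1.28 (case) and 1.08
#' (control) mm, ages near 11 years, mostly boys, and clinical scores with
#' case/control means of 64.52/46.95 (inattention), 71.67/50.00
#' (hyperactivity-impulsivity) and 69.19/48.40 (DSM total), the
#' hyperactivity-impulsivity score being coupled to the realized mid-section
#' profile shape.
#'
#' @param nPerGroup subjects per group.
#' @param base base \linkS4class{SulcusSpec}.
#' @param groupEffects list of effects; each is a list with \code{target}
#'   ("depth", "profile", "thickness", "span" or "length"), \code{amplitude}
#'   in mm, optional \code{window} (y interval; global when absent) and
#'   \code{group} (default "case").
#' @param subjectVariation list of between-subject SDs; see
#'   \linkS4class{CohortSpec}.
#' @param covariateModel age/gender distributions per group and covariate
#'   slopes.
#' @param scoreModel clinical-score moments per group and the score-shape
#'   coupling.
#' @param seed RNG seed.
#' @return A \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nPerGroup = 21L,
                       base = sulcusSpec(noiseSd = 0.05),
                       groupEffects = list(
                         list(target = "depth", amplitude = 1.33, group = "case"),
                         list(target = "thickness", amplitude = 0.60, group = "case"),
                         list(target = "profile", amplitude = 1.2,
                              window = c(45, 60), group = "case")),
                       subjectVariation = list(
                         depthOffset = c(case = 1.28, control = 1.08),
                         depthSmooth = 0.8, profileSmooth = 1.0,
                         thickness = c(case = 0.33, control = 0.59),
                         span = 0.16, length = 9.3, nModes = 6L),
                       covariateModel = list(
                         ageMean = c(case = 130.14, control = 139.19),
                         ageSd = c(case = 23.83, control = 22.71),
                         pBoy = c(case = 18 / 21, control = 15 / 21),
                         slopes = list(depthAge = 0.01)),
                       scoreModel = list(
                         inattention = list(mean = c(case = 64.52, control = 46.95),
                                            sd = c(case = 9.27, control = 5.63)),
                         hyperactivity_impulsivity = list(
                           mean = c(case = 71.67, control = 50.00),
                           sd = c(case = 14.00, control = 10.93)),
                         dsm_total = list(mean = c(case = 69.19, control = 48.40),
                                          sd = c(case = 10.68, control = 8.22)),
                         coupling = list(score = "hyperactivity_impulsivity",
                                         window = c(45, 60), coeff = 6)),
                       seed = 1L) {
  obj <- new("CohortSpec", nPerGroup = as.integer(nPerGroup), base = base,
    groupEffects = groupEffects, subjectVariation = subjectVariation,
    covariateModel = covariateModel, scoreModel = scoreModel,
    seed = as.integer(seed))
  validObject(obj)
  obj
}

effectTermFn <- function(effects, target, group) {
  effs <- Filter(function(e) identical(e$target, target) &&
                   identical(e$group %||% "case", group), effects)
  if (!length(effs)) return(function(y) rep(0, length(y)))
  fns <- lapply(effs, function(e) {
    if (is.null(e$window)) {
      amp <- e$amplitude
      function(y) rep(amp, length(y))
    } else {
      bump <- windowBump(e$window)
      amp <- e$amplitude
      function(y) amp * bump(y)
    }
  })
  function(y) Reduce(`+`, lapply(fns, function(f) f(y)))
}

scalarEffect <- function(effects, target, group) {
  effs <- Filter(function(e) identical(e$target, target) &&
                   identical(e$group %||% "case", group), effects)
  sum(vapply(effs, function(e) e$amplitude, numeric(1)))
}

#' Generate a synthetic cohort of sulcal meshes
#'
#' Draws per-subject sulci from a \linkS4class{CohortSpec}: smooth random
#' perturbations of the base depth and profile functions, group effects in the
#' specified targets/windows, covariate slopes, and clinical scores with the
#' specified group moments, optionally coupled to the realized shape. Every
#' random draw is governed by the spec seed, so identical specs reproduce the
#' cohort exactly.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param hemisphere hemisphere tag stored per mesh ("L" by default).
#' @return A \linkS4class{SulcalCohort}: meshes, the cohort table and a
#'   ground-truth record (the spec plus realized per-subject true metrics).
#' @export
generateCohort <- function(spec, hemisphere = "L") {
  nv <- spec@subjectVariation
  cm <- spec@covariateModel
  sm <- spec@scoreModel
  n <- 2L * spec@nPerGroup
  groups <- rep(c("case", "control"), each = spec@nPerGroup)
  ids <- sprintf("S%03d", seq_len(n))
  ageRef <- mean(c(perGroup(cm$ageMean, "case"), perGroup(cm$ageMean, "control")))
  depthAgeSlope <- cm$slopes$depthAge %||% 0

  out <- withSeed(spec@seed, {
    meshes <- vector("list", n)
    rows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      g <- groups[i]
      age <- rnorm(1, perGroup(cm$ageMean, g), perGroup(cm$ageSd, g))
      gender <- rbinom(1, 1, perGroup(cm$pBoy, g))

      depthOff <- rnorm(1, 0, perGroup(nv$depthOffset, g)) +
        depthAgeSlope * (age - ageRef)
      depthWiggle <- randomSmoothFn(nv$depthSmooth %||% 0, nv$nModes %||% 6L)
      profWiggle <- randomSmoothFn(nv$profileSmooth %||% 0, nv$nModes %||% 6L)
      thickOff <- rnorm(1, 0, perGroup(nv$thickness, g))
      spanOff <- rnorm(1, 0, nv$span %||% 0)
      lenOff <- rnorm(1, 0, nv$length %||% 0)

      depthEff <- effectTermFn(spec@groupEffects, "depth", g)
      profEff <- effectTermFn(spec@groupEffects, "profile", g)
      thickEff <- scalarEffect(spec@groupEffects, "thickness", g)
      spanEff <- scalarEffect(spec@groupEffects, "span", g)
      lenEff <- scalarEffect(spec@groupEffects, "length", g)

      base <- spec@base
      baseDepth <- base@depthFn; baseProf <- base@profileFn
      baseThick <- base@thicknessFn
      subjDepthFn <- local({
        dOff <- depthOff; dW <- depthWiggle; dE <- depthEff; bD <- baseDepth
        function(y) pmax(bD(y) + dOff + dW(y) + dE(y), 1)
      })
      subjProfFn <- local({
        pW <- profWiggle; pE <- profEff; bP <- baseProf
        function(y) bP(y) + pW(y) + pE(y)
      })
      subjThickFn <- local({
        tOff <- thickOff + thickEff; bT <- baseThick
        function(y) pmax(bT(y) + tOff, 0.5)
      })
      subjSpec <- sulcusSpec(
        length = max(base@length + lenOff + lenEff, 40),
        depthFn = subjDepthFn, profileFn = subjProfFn,
        span = max(base@span + spanOff + spanEff, 0.5),
        thicknessFn = subjThickFn,
        meshResolution = base@meshResolution,
        seed = (spec@seed + 1009L * i) %% 2147483647L,
        noiseSd = base@noiseSd)

      scores <- list()
      for (nm in setdiff(names(sm), "coupling"))
        scores[[nm]] <- rnorm(1, perGroup(sm[[nm]]$mean, g), perGroup(sm[[nm]]$sd, g))
      cp <- sm$coupling
      if (!is.null(cp) && (cp$coeff %||% 0) != 0) {
        yw <- seq(cp$window[1], cp$window[2], length.out = 101)
        dev <- mean(subjProfFn(yw) - baseProf(yw))
        scores[[cp$score]] <- scores[[cp$score]] + cp$coeff * dev
      }

      meshes[[i]] <- generateSulcus(subjSpec,
        meta = list(subject_id = ids[i], group = g, hemisphere = hemisphere))
      gt <- meshes[[i]]@meta$groundTruth
      rows[[i]] <- data.frame(subject_id = ids[i], group = g,
        age_months = age, gender = gender,
        inattention = scores$inattention,
        hyperactivity_impulsivity = scores$hyperactivity_impulsivity,
        dsm_total = scores$dsm_total, stringsAsFactors = FALSE)
      truth[[i]] <- list(subject_id = ids[i], group = g,
        averageDepth = gt$averageDepth, maxDepth = gt$maxDepth,
        profileCurve = gt$profileCurve, depthCurve = gt$depthCurve,
        thickness = gt$thickness, span = gt$span, length = gt$length)
    }
    list(meshes = meshes, rows = rows, truth = truth)
  })
  tab <- validateCohortTable(do.call(rbind, out$rows))
  new("SulcalCohort", meshes = out$meshes, table = tab,
      groundTruth = list(spec = spec, subjects = out$truth))
}

#' Simulate position-wise profile curves without meshing
#'
#' Curve-level companion of \code{\link{generateCohort}} used for statistical
#' calibration (type-I error and power of the position-wise analysis): each
#' subject's curve is a smooth random function (Fourier modes, pointwise SD
#' \code{smoothSd}) plus independent per-position noise (\code{noiseSd}),
#' with an optional constant group effect inside a y window and an optional
#' linear age slope. The defaults put most of the between-subject variance in
#' the smooth component (correlation length about 12 positions, the scale of
#' sulcal undulations such as the hand knob) with a smaller independent
#' per-position term for binning/measurement noise; the total per-position SD
#' is sqrt(1.05^2 + 0.55^2) ~ 1.19 mm.
#'
#' @param nPerGroup subjects per group.
#' @param P number of positions.
#' @param effectWindow y interval c(lo, hi) carrying the case-group effect,
#'   or NULL for a null cohort.
#' @param amplitude effect size inside the window (mm).
#' @param smoothSd pointwise SD of the smooth between-subject variation (mm).
#' @param noiseSd SD of independent per-position noise (mm).
#' @param nModes number of Fourier modes of the smooth part.
#' @param ageSlope curve change per month of age (mm/month).
#' @param seed RNG seed.
#' @return list with \code{curves} (2*nPerGroup x P matrix) and
#'   \code{cohort} (a valid cohort table).
#' @export
simulateProfileCurves <- function(nPerGroup = 21L, P = 100L, effectWindow = NULL,
                                  amplitude = 0, smoothSd = 1.05, noiseSd = 0.55,
                                  nModes = 8L, ageSlope = 0, seed = 1L) {
  n <- 2L * nPerGroup
  groups <- rep(c("case", "control"), each = nPerGroup)
  y <- seq_len(P) * 100 / P
  withSeed(seed, {
    ages <- rnorm(n, 134.7, 23.3)
    genders <- rbinom(n, 1, 0.78)
    curves <- matrix(0, n, P)
    for (i in seq_len(n)) {
      sm <- randomSmoothFn(smoothSd, nModes)
      curves[i, ] <- sm(y) + rnorm(P, 0, noiseSd) + ageSlope * (ages[i] - 134.7)
      if (!is.null(effectWindow) && groups[i] == "case")
        curves[i, ] <- curves[i, ] +
          amplitude * (y >= effectWindow[1] & y <= effectWindow[2])
    }
    cohort <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)), group = groups,
      age_months = ages, gender = genders,
      inattention = rnorm(n, ifelse(groups == "case", 64.52, 46.95),
                          ifelse(groups == "case", 9.27, 5.63)),
      hyperactivity_impulsivity = rnorm(n, ifelse(groups == "case", 71.67, 50),
                                        ifelse(groups == "case", 14, 10.93)),
      dsm_total = rnorm(n, ifelse(groups == "case", 69.19, 48.40),
                        ifelse(groups == "case", 10.68, 8.22)),
      stringsAsFactors = FALSE)
    rownames(curves) <- cohort$subject_id
    list(curves = curves, cohort = validateCohortTable(cohort))
  })
}

#' Plant an accessory fin on a mesh (testing utility)
#'
#' Attaches a small rectangular fin at a right angle to an interior edge of
#' the sheet, reproducing the accessory folds that
#' \code{\link{removeAccessoryBranches}} prunes. The junction edge becomes
#' non-manifold (three adjacent triangles), exactly as when an accessory
#' sulcal fold meets the main sheet.
#'
#' @param mesh a \linkS4class{SulcalMesh}.
#' @param finLength fin extent from the junction (mm).
#' @param edge optional integer(2): the interior edge to attach to; chosen
#'   near the mesh barycenter when NULL.
#' @return list with \code{mesh} (unvalidated \linkS4class{SulcalMesh}),
#'   \code{finFaces} (row indices of the fin triangles) and
#'   \code{finVertices}.
#' @export
plantAccessoryFin <- function(mesh, finLength = 3, edge = NULL) {
  V <- mesh@vertices; F <- mesh@triangles
  if (is.null(edge)) {
    ec <- edgeUseCounts(F)
    interiorEdges <- ec$edges[ec$count == 2L, , drop = FALSE]
    bset <- boundaryVertexSet(F)
    ok <- !(interiorEdges[, 1] %in% bset) & !(interiorEdges[, 2] %in% bset)
    interiorEdges <- interiorEdges[ok, , drop = FALSE]
    ctr <- colMeans(V)
    mid <- (V[interiorEdges[, 1], , drop = FALSE] +
            V[interiorEdges[, 2], , drop = FALSE]) / 2
    edge <- interiorEdges[which.min(rowSums(sweep(mid, 2, ctr)^2)), ]
  }
  a <- edge[1]; b <- edge[2]
  nrm <- vertexNormals(V, F)
  dir <- (nrm[a, ] + nrm[b, ])
  dir <- dir / sqrt(sum(dir^2))
  a2 <- V[a, ] + finLength * dir
  b2 <- V[b, ] + finLength * dir
  V2 <- rbind(V, a2, b2)
  dimnames(V2) <- NULL
  ia <- nrow(V) + 1L; ib <- nrow(V) + 2L
  F2 <- rbind(F, c(a, b, ia), c(b, ib, ia))
  out <- mesh
  out@vertices <- V2
  out@triangles <- matrix(as.integer(F2), ncol = 3)
  out@nodeFields <- lapply(mesh@nodeFields, function(f) c(f, NA_real_, NA_real_))
  list(mesh = out, finFaces = c(nrow(F) + 1L, nrow(F) + 2L),
       finVertices = c(ia, ib))
}
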