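# Shape measurements on (parameterized) sulcal meshes: the inertial plane and
# signed-distance sulcal profile, the depth-position profile, and the six
# global measures (length, average/max depth, span, thickness, surface area).

#' @describeIn morphometry-generics Inertial plane of a sulcal mesh: the
#'   vertex barycenter and the eigenvectors of the vertex covariance
#'   A = Sc Sc' ordered by decreasing eigenvalue. u1 and u2 span the plane
#'   (the main orientation of the sulcus); u3 is its normal. The sign of u3
#'   points from the posterior toward the anterior gyral bank when bank
#'   companions are attached (keeping signs comparable across subjects);
#'   otherwise it is fixed so that the sum of cubed signed distances is
#'   non-negative (first non-zero component positive on ties). Use
#'   \code{weights = "area"} for a vertex-area-weighted barycenter and
#'   covariance, more robust to non-uniform mesh sampling.
#' @param weights "uniform" (vertex-based, the default) or "area".
#' @export
setMethod("inertialPlane", "SulcalMesh", function(object,
    weights = c("uniform", "area")) {
  weights <- match.arg(weights)
  V <- object@vertices
  if (nrow(V) < 3L) stop("need at least 3 vertices")
  if (weights == "uniform") {
    wv <- rep(1, nrow(V))
  } else {
    ar <- triangleAreas(V, object@triangles)
    wv <- numeric(nrow(V))
    for (j in 1:3) {
      acc <- rowsum(ar / 3, object@triangles[, j])
      wv[as.integer(rownames(acc))] <- wv[as.integer(rownames(acc))] + acc
    }
  }
  wv <- wv / sum(wv)
  bary <- colSums(V * wv)
  Vc <- sweep(V, 2, bary)
  A <- crossprod(Vc * sqrt(wv))
  eg <- eigen(A, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1))
    stop("vertex set is (near-)collinear; inertial plane undefined")
  axes <- eg$vectors
  # u3 sign convention. The anatomical rule (normal points from the
  # posterior toward the anterior gyral bank) keeps the sign consistent
  # across subjects, which signed group comparisons require; the skewness
  # rule sum(d^3) >= 0 is the fallback when no banks are attached, and is
  # unstable when the profile is nearly antisymmetric.
  oriented <- FALSE
  cp <- object@companions
  if (!is.null(cp$bankAnterior) && !is.null(cp$bankPosterior)) {
    dir <- colMeans(cp$bankAnterior$vertices) -
      colMeans(cp$bankPosterior$vertices)
    dt <- sum(dir * axes[, 3])
    if (abs(dt) > 1e-9 * sqrt(sum(dir^2))) {
      if (dt < 0) axes[, 3] <- -axes[, 3]
      oriented <- TRUE
    }
  }
  if (!oriented) {
    d <- as.numeric(Vc %*% axes[, 3])
    s3 <- sum(d^3)
    if (abs(s3) > 1e-9) {
      if (s3 < 0) axes[, 3] <- -axes[, 3]
    } else {
      nz <- which(abs(axes[, 3]) > 1e-12)[1]
      if (axes[nz, 3] < 0) axes[, 3] <- -axes[, 3]
    }
  }
  # keep a right-handed frame
  if (det(axes) < 0) axes[, 1] <- -axes[, 1]
  new("InertialPlane", barycenter = bary, axes = axes, eigenvalues = eg$values)
})

setMethod("inertialPlane", "ParameterizedSulcus", function(object, ...)
  inertialPlane(object@mesh, ...))

#' Signed distances to the inertial plane
#'
#' d_i = (n_i - nbar) . u3 for every mesh node n_i, in mm. With uniform
#' weights the distances sum to zero exactly (centering identity).
#'
#' @param mesh a \linkS4class{SulcalMesh} or \linkS4class{ParameterizedSulcus}.
#' @param plane the \linkS4class{InertialPlane} of the same mesh (computed
#'   when NULL).
#' @return Numeric vector of per-node signed distances.
#' @export
signedDistances <- function(mesh, plane = NULL) {
  if (is(mesh, "ParameterizedSulcus")) mesh <- mesh@mesh
  if (is.null(plane)) plane <- inertialPlane(mesh)
  as.numeric(sweep(mesh@vertices, 2, plane@barycenter) %*% plane@axes[, 3])
}

# Position p covers y in ((p-1) * 100/P, p * 100/P] and is reported at
# y = p * 100/P; for P = 100 the position index and the y value coincide.
positionBin <- function(y, P) pmin(pmax(as.integer(ceiling(y * P / 100)), 1L), P)

#' Sulcal profile curve
#'
#' The sulcal profile is the mean signed distance to the inertial plane of
#' the nodes at each y position: nodes are assigned to the nearest of P
#' equal y bins (position p represents y = p * 100 / P) and averaged. Empty
#' bins are filled by linear interpolation and flagged.
#'
#' @param ps a \linkS4class{ParameterizedSulcus}.
#' @param plane optional precomputed \linkS4class{InertialPlane}.
#' @param P number of positions (default 100).
#' @return A \linkS4class{ProfileCurve}.
#' @export
profileCurve <- function(ps, plane = NULL, P = 100L) {
  d <- signedDistances(ps@mesh, plane)
  bin <- positionBin(ps@yField, P)
  sums <- rowsum(d, bin)
  cnts <- rowsum(rep(1, length(d)), bin)
  vals <- rep(NA_real_, P)
  counts <- integer(P)
  vals[as.integer(rownames(sums))] <- sums / cnts
  counts[as.integer(rownames(cnts))] <- as.integer(cnts)
  empty <- is.na(vals)
  if (mean(empty) > 0.2)
    stop(sprintf("%.0f%% of profile bins are empty; mesh resolution too ",
                 100 * mean(empty)), "coarse for P = ", P)
  if (any(empty)) {
    filled <- which(!empty)
    vals[empty] <- approx(filled, vals[filled], xout = which(empty),
                          rule = 2)$y
  }
  new("ProfileCurve", positions = seq_len(P), values = vals,
      nodeDistances = d, counts = counts, interpolated = empty)
}

#' Depth-position profile (DPP)
#'
#' Sulcal depth as a function of the y coordinate at P successive positions.
#' In geodesic mode (default) the depth at y is the arclength of the
#' y-isoparameter polyline traced across the mesh between the top ridge
#' (brain envelope) and the fundus; in euclidean mode it is the straight
#' 3-D distance between the top-ridge and bottom-ridge points at that y.
#' Positions without level-set support take the nearest supported value and
#' are flagged.
#'
#' @param ps a \linkS4class{ParameterizedSulcus}.
#' @param P number of positions.
#' @param mode "geodesic" or "euclidean".
#' @return A \linkS4class{DepthPositionProfile}.
#' @export
depthPositionProfile <- function(ps, P = 100L, mode = c("geodesic", "euclidean")) {
  mode <- match.arg(mode)
  yPos <- seq_len(P) * 100 / P
  depth <- rep(NA_real_, P)
  V <- ps@mesh@vertices; F <- ps@mesh@triangles
  f1 <- ps@yField[F[, 1]]; f2 <- ps@yField[F[, 2]]; f3 <- ps@yField[F[, 3]]
  V1 <- V[F[, 1], , drop = FALSE]
  V2 <- V[F[, 2], , drop = FALSE]
  V3 <- V[F[, 3], , drop = FALSE]
  ec <- edgeUseCounts(F)
  bKeys <- ec$key[!duplicated(ec$key)][ec$count == 1L]
  b12 <- ec$faceEdgeKeys[, 1] %in% bKeys
  b23 <- ec$faceEdgeKeys[, 2] %in% bKeys
  b31 <- ec$faceEdgeKeys[, 3] %in% bKeys
  crossPt <- function(fa, fb, Va, Vb, yp) {
    tt <- (yp - fa) / (fb - fa)
    Va + tt * (Vb - Va)
  }
  for (p in seq_len(P)) {
    yp <- yPos[p]
    if (any(f1 == yp | f2 == yp | f3 == yp)) yp <- yp + 1e-9
    m12 <- (f1 - yp) * (f2 - yp) < 0
    m23 <- (f2 - yp) * (f3 - yp) < 0
    m31 <- (f3 - yp) * (f1 - yp) < 0
    two <- (m12 + m23 + m31) == 2L
    if (!any(two)) next
    idx <- which(two)
    m12t <- m12[idx]; m23t <- m23[idx]; m31t <- m31[idx]
    p12 <- crossPt(f1[idx], f2[idx], V1[idx, , drop = FALSE],
                   V2[idx, , drop = FALSE], yp)
    p23 <- crossPt(f2[idx], f3[idx], V2[idx, , drop = FALSE],
                   V3[idx, , drop = FALSE], yp)
    p31 <- crossPt(f3[idx], f1[idx], V3[idx, , drop = FALSE],
                   V1[idx, , drop = FALSE], yp)
    if (mode == "geodesic") {
      A <- matrix(NA_real_, length(idx), 3); B <- A
      A[m12t, ] <- p12[m12t, , drop = FALSE]
      A[!m12t, ] <- p23[!m12t, , drop = FALSE]
      B[m31t, ] <- p31[m31t, , drop = FALSE]
      B[!m31t, ] <- p23[!m31t, , drop = FALSE]
      depth[p] <- sum(sqrt(rowSums((A - B)^2)))
    } else {
      # endpoints of the isoparameter polyline: its crossings of boundary
      # edges (one on the envelope ridge, one on the fundus)
      ends <- rbind(p12[m12t & b12[idx], , drop = FALSE],
                    p23[m23t & b23[idx], , drop = FALSE],
                    p31[m31t & b31[idx], , drop = FALSE])
      if (nrow(ends) == 2L)
        depth[p] <- sqrt(sum((ends[1, ] - ends[2, ])^2))
    }
  }
  flagged <- is.na(depth)
  if (all(flagged)) stop("no position has level-set support; is the mesh parameterized?")
  if (any(flagged)) {
    ok <- which(!flagged)
    nearest <- ok[vapply(which(flagged), function(p)
      which.min(abs(ok - p)), integer(1))]
    depth[flagged] <- depth[nearest]
  }
  new("DepthPositionProfile", positions = seq_len(P), depth = depth,
      mode = mode, flagged = flagged)
}

#' Average and maximum sulcal depth
#'
#' @param dpp a \linkS4class{DepthPositionProfile}.
#' @return Named numeric: \code{averageDepth} (mean over positions) and
#'   \code{maxDepth}.
#' @export
depthSummary <- function(dpp) {
  c(averageDepth = mean(dpp@depth), maxDepth = max(dpp@depth))
}

#' @describeIn morphometry-generics Sulcal length: the mean of the polyline
#'   arclengths of the exterior (top ridge) and interior (bottom ridge)
#'   sulcal boundaries, in mm.
#' @export
setMethod("sulcalLength", "SulcalMesh", function(object) {
  mean(c(polylineLength(object@vertices, object@topRidge),
         polylineLength(object@vertices, object@bottomRidge)))
})

setMethod("sulcalLength", "ParameterizedSulcus", function(object)
  sulcalLength(object@mesh))

#' @describeIn morphometry-generics Total surface area: the sum of all
#'   triangle areas, in mm^2.
#' @export
setMethod("surfaceArea", "SulcalMesh", function(object)
  sum(triangleAreas(object@vertices, object@triangles)))

setMethod("surfaceArea", "ParameterizedSulcus", function(object)
  surfaceArea(object@mesh))

spanAlongNormals <- function(mesh, surfA, surfB, maxNodes = Inf) {
  V <- mesh@vertices
  nrm <- vertexNormals(V, mesh@triangles)
  idx <- seq_len(nrow(V))
  if (is.finite(maxNodes) && maxNodes < length(idx))
    idx <- idx[round(seq(1, length(idx), length.out = maxNodes))]
  vals <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    tA <- lineMeshIntersect(V[i, ], nrm[i, ], surfA$vertices, surfA$triangles)
    tB <- lineMeshIntersect(V[i, ], nrm[i, ], surfB$vertices, surfB$triangles)
    if (!is.na(tA) && !is.na(tB)) vals[k] <- abs(tA - tB)
  }
  valid <- !is.na(vals)
  list(values = vals, validFraction = mean(valid))
}

#' @describeIn morphometry-generics Average sulcal span: the bank-to-bank
#'   3-D distance along the normal direction of the medial sulcal mesh,
#'   averaged over the nodes whose normal line intersects both gyral banks
#'   (companions \code{bankAnterior} and \code{bankPosterior}). The valid
#'   node fraction is attached as attribute \code{validFraction}; fewer than
#'   50 percent valid nodes is an error.
#' @param maxNodes cap on the number of nodes sampled (all by default).
#' @export
setMethod("sulcalSpan", "SulcalMesh", function(object, maxNodes = Inf) {
  cp <- object@companions
  if (is.null(cp$bankAnterior) || is.null(cp$bankPosterior))
    stop("sulcalSpan needs bankAnterior and bankPosterior companion surfaces")
  res <- spanAlongNormals(object, cp$bankAnterior, cp$bankPosterior, maxNodes)
  if (res$validFraction < 0.5)
    stop(sprintf("only %.0f%% of nodes have a bank intersection on both sides",
                 100 * res$validFraction))
  structure(mean(res$values, na.rm = TRUE), validFraction = res$validFraction)
})

setMethod("sulcalSpan", "ParameterizedSulcus", function(object, ...)
  sulcalSpan(object@mesh, ...))

#' @describeIn morphometry-generics Average cortical thickness along the
#'   sulcus: either the normal-line distance between the CSF/GM and GM/WM
#'   interface companions (\code{interfaceOuter}/\code{interfaceInner}),
#'   averaged over nodes with both intersections, or the mean of a supplied
#'   per-node \code{thickness} field. \code{method = "auto"} prefers the
#'   interfaces when present.
#' @param method "auto", "interfaces" or "field".
#' @export
setMethod("corticalThickness", "SulcalMesh", function(object,
    method = c("auto", "interfaces", "field"), maxNodes = Inf) {
  method <- match.arg(method)
  cp <- object@companions
  hasIfc <- !is.null(cp$interfaceInner) && !is.null(cp$interfaceOuter)
  hasField <- !is.null(object@nodeFields$thickness)
  if (method == "auto") method <- if (hasIfc) "interfaces" else "field"
  if (method == "interfaces") {
    if (!hasIfc) stop("interfaceInner/interfaceOuter companions are missing")
    res <- spanAlongNormals(object, cp$interfaceInner, cp$interfaceOuter, maxNodes)
    if (res$validFraction < 0.5)
      stop("fewer than half of the nodes intersect both interfaces")
    structure(mean(res$values, na.rm = TRUE), validFraction = res$validFraction)
  } else {
    if (!hasField) stop("no thickness source: neither interface companions ",
                        "nor a per-node thickness field present")
    mean(object@nodeFields$thickness)
  }
})

setMethod("corticalThickness", "ParameterizedSulcus", function(object, ...)
  corticalThickness(object@mesh, ...))

#' Compute all six global shape measures
#'
#' @param ps a \linkS4class{ParameterizedSulcus} (the depth measures need the
#'   y field).
#' @param P positions of the depth-position profile.
#' @param depthMode "geodesic" or "euclidean".
#' @param spanMaxNodes,thicknessMethod passed to \code{\link{sulcalSpan}} and
#'   \code{\link{corticalThickness}}; span/thickness are NULL when their
#'   inputs (companion surfaces, thickness field) are absent.
#' @return A \linkS4class{GlobalMetrics}.
#' @export
globalMetrics <- function(ps, P = 100L, depthMode = "geodesic",
                          spanMaxNodes = Inf, thicknessMethod = "auto") {
  dpp <- depthPositionProfile(ps, P = P, mode = depthMode)
  ds <- depthSummary(dpp)
  mesh <- ps@mesh
  cp <- mesh@companions
  span <- if (!is.null(cp$bankAnterior) && !is.null(cp$bankPosterior))
    as.numeric(sulcalSpan(mesh, maxNodes = spanMaxNodes)) else NULL
  canThick <- (!is.null(cp$interfaceInner) && !is.null(cp$interfaceOuter)) ||
    !is.null(mesh@nodeFields$thickness)
  thick <- if (canThick)
    as.numeric(corticalThickness(mesh, method = thicknessMethod,
                                 maxNodes = spanMaxNodes)) else NULL
  new("GlobalMetrics", averageLength = sulcalLength(mesh),
      averageDepth = unname(ds["averageDepth"]), maxDepth = unname(ds["maxDepth"]),
      averageSpan = span, averageThickness = thick,
      surfaceArea = surfaceArea(mesh))
}
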