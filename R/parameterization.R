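# Harmonic (steady-state heat equation) parameterization of sulcal meshes.
#
# The two coordinate fields are the steady states of surface heat diffusion
# with the ridges/endpoints as constant sources, i.e. solutions of the
# Laplace equation with Dirichlet boundary data, discretized with the
# cotangent-weight Laplacian. x runs from the top ridge (brain envelope, 0)
# to the bottom ridge (fundus, 100); y from the superior (0) to the inferior
# (100) end. The y Dirichlet data sit on the end walls -- the boundary arcs
# joining the two ridges at each extremity -- which degenerate to the single
# endpoint vertices when the sulcus tapers to a point.

# Sparse cotangent-weight Laplacian (positive semi-definite, L = D - W).
cotanLaplacian <- function(V, F, weights = c("cotangent", "uniform")) {
  weights <- match.arg(weights)
  n <- nrow(V)
  if (weights == "cotangent") {
    ar <- triangleAreas(V, F)
    if (any(ar < 1e-12)) {
      warning("degenerate triangles; falling back to uniform Laplacian weights")
      return(cotanLaplacian(V, F, "uniform"))
    }
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    corner <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
    for (cr in corner) {
      k <- F[, cr[3]]; i <- F[, cr[1]]; j <- F[, cr[2]]
      a <- V[i, , drop = FALSE] - V[k, , drop = FALSE]
      b <- V[j, , drop = FALSE] - V[k, , drop = FALSE]
      cot <- rowSums(a * b) / rowNorms(rowCross(a, b))
      ii <- c(ii, i, j); jj <- c(jj, j, i); ww <- c(ww, cot / 2, cot / 2)
    }
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  } else {
    ec <- edgeUseCounts(F)
    e <- ec$edges
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
  }
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Solve the steady-state heat equation on a mesh
#'
#' Computes the harmonic field with the given Dirichlet boundary data: the
#' cotangent-weighted discrete Laplacian is zero at every free vertex and the
#' prescribed values are held exactly. This is the steady state of surface
#' heat diffusion with the prescribed vertices as constant heat sources.
#'
#' @param mesh a \linkS4class{SulcalMesh}.
#' @param boundaryValues named numeric vector; names are vertex indices,
#'   values the Dirichlet data. At least two distinct values are required.
#' @param weights "cotangent" (default) or "uniform"; degenerate triangles
#'   trigger an automatic fallback to uniform weights with a warning.
#' @return Numeric vector with one value per vertex. Interior values satisfy
#'   the discrete maximum principle whenever all weights are non-negative.
#' @export
solveHarmonicField <- function(mesh, boundaryValues,
                               weights = c("cotangent", "uniform")) {
  V <- mesh@vertices; F <- mesh@triangles
  bIdx <- as.integer(names(boundaryValues))
  if (length(bIdx) == 0L) stop("boundaryValues must not be empty")
  if (anyNA(bIdx) || any(bIdx < 1L) || any(bIdx > nrow(V)))
    stop("boundaryValues names must be valid vertex indices")
  if (length(unique(boundaryValues)) < 2L)
    stop("boundaryValues must contain at least two distinct values")
  L <- cotanLaplacian(V, F, match.arg(weights))
  field <- numeric(nrow(V))
  field[bIdx] <- boundaryValues
  iIdx <- setdiff(seq_len(nrow(V)), bIdx)
  if (length(iIdx)) {
    rhs <- -L[iIdx, bIdx, drop = FALSE] %*% boundaryValues
    sol <- tryCatch(Matrix::solve(L[iIdx, iIdx], rhs),
      error = function(e) stop("singular harmonic system (disconnected ",
                               "interior?): ", conditionMessage(e)))
    field[iIdx] <- as.numeric(sol)
  }
  field
}

# Identify the two end-wall vertex sets: the boundary components that remain
# after removing the ridge interiors, one containing each endpoint.
endWallSets <- function(mesh) {
  F <- mesh@triangles
  be <- boundaryEdges(F)
  tr <- mesh@topRidge; br <- mesh@bottomRidge
  ridgeInterior <- c(tr[-c(1L, length(tr))], br[-c(1L, length(br))])
  allowed <- !(be[, 1] %in% ridgeInterior) & !(be[, 2] %in% ridgeInterior)
  we <- be[allowed, , drop = FALSE]
  n <- nrow(mesh@vertices)
  comp <- unionFind(n, we)
  sup <- which(comp == comp[mesh@endpointSuperior])
  inf <- which(comp == comp[mesh@endpointInferior])
  wallVerts <- unique(as.vector(we))
  sup <- intersect(sup, c(wallVerts, mesh@endpointSuperior))
  inf <- intersect(inf, c(wallVerts, mesh@endpointInferior))
  if (length(intersect(sup, inf)))
    stop("superior and inferior end walls are connected; check ridge labels")
  list(superior = union(sup, mesh@endpointSuperior),
       inferior = union(inf, mesh@endpointInferior))
}

#' Parameterize a sulcal mesh
#'
#' Computes the (x, y) harmonic coordinate fields: x with the top ridge at 0
#' and the bottom ridge at 100; y with the superior end wall at 0 and the
#' inferior end wall at 100 (both ridges free). Both constructions are
#' intrinsic, hence invariant under rigid motion and uniform scaling of the
#' mesh.
#'
#' @param mesh a \linkS4class{SulcalMesh}.
#' @param weights Laplacian weighting, see \code{\link{solveHarmonicField}}.
#' @return A \linkS4class{ParameterizedSulcus} with stage "raw".
#' @export
setMethod("parameterize", "SulcalMesh", function(mesh,
    weights = c("cotangent", "uniform")) {
  weights <- match.arg(weights)
  xbv <- c(setNames(rep(0, length(mesh@topRidge)), mesh@topRidge),
           setNames(rep(100, length(mesh@bottomRidge)), mesh@bottomRidge))
  xf <- solveHarmonicField(mesh, xbv, weights)
  walls <- endWallSets(mesh)
  ybv <- c(setNames(rep(0, length(walls$superior)), walls$superior),
           setNames(rep(100, length(walls$inferior)), walls$inferior))
  yf <- solveHarmonicField(mesh, ybv, weights)
  new("ParameterizedSulcus", mesh = mesh,
      xField = pmin(pmax(xf, 0), 100), yField = pmin(pmax(yf, 0), 100),
      stage = "raw")
})

#' Detect the L1/L2 landmarks on a sulcal profile
#'
#' L1 is the position of the global maximum of the profile curve restricted
#' to the central half of the sulcus (y in [25, 75]); L2 is the first local
#' minimum after L1 (the global minimum beyond L1 when no interior local
#' minimum exists). Ties break toward smaller y. Monotone or constant
#' profiles have no stable extremum and are flagged undefined; such subjects
#' skip reparameterization.
#'
#' @param profile a \linkS4class{ProfileCurve}.
#' @return list with \code{L1}, \code{L2} (y units, NA when undefined) and
#'   \code{defined}.
#' @export
detectLandmarks <- function(profile) {
  v <- profile@values
  P <- length(v)
  if (P < 3L) stop("profile needs at least 3 positions")
  yOf <- function(p) p * 100 / P
  undefined <- list(L1 = NA_real_, L2 = NA_real_, defined = FALSE)
  if (max(v) - min(v) < 1e-9) return(undefined)
  dv <- diff(v)
  if (all(dv >= 0) || all(dv <= 0)) return(undefined)  # monotone profile
  central <- which(yOf(seq_len(P)) >= 25 & yOf(seq_len(P)) <= 75)
  p1 <- central[which.max(v[central])]
  p2 <- NA_integer_
  for (i in seq.int(p1 + 1L, P - 1L)) {
    if (i <= 1L) next
    if (v[i] <= v[i - 1L] && v[i] <= v[i + 1L] &&
        (v[i] < v[i - 1L] || v[i] < v[i + 1L])) { p2 <- i; break }
  }
  if (is.na(p2)) {
    rest <- seq.int(p1 + 1L, P)
    if (!length(rest)) return(undefined)
    p2 <- rest[which.min(v[rest])]
  }
  L1 <- yOf(p1); L2 <- yOf(p2)
  # landmarks on the domain boundary cannot anchor the piecewise-linear map
  list(L1 = L1, L2 = L2, defined = (L1 > 0 && L2 < 100))
}

#' Average landmark positions across subjects
#'
#' Arithmetic mean of the L1 and L2 positions over the subjects with defined
#' landmarks (the matching target used for reparameterization within a
#' group). Subjects with undefined landmarks are excluded with a warning.
#'
#' @param landmarkList list of landmark lists as returned by
#'   \code{\link{detectLandmarks}} (or numeric c(L1, L2) vectors).
#' @return list with \code{L1}, \code{L2} and \code{nExcluded}.
#' @export
groupTargetLandmarks <- function(landmarkList) {
  lm <- lapply(landmarkList, function(x) {
    if (is.list(x)) c(x$L1, x$L2) else x
  })
  ok <- vapply(lm, function(x) length(x) == 2L && !anyNA(x), logical(1))
  if (!any(ok)) stop("no subject has defined landmarks")
  if (any(!ok))
    warning(sum(!ok), " subject(s) with undefined landmarks excluded from ",
            "the landmark average")
  m <- colMeans(do.call(rbind, lm[ok]))
  list(L1 = m[1], L2 = m[2], nExcluded = sum(!ok))
}

#' Reparameterize y by piecewise-linear landmark matching
#'
#' Rescales the y coordinate with the continuous piecewise-linear map taking
#' (0, L1, L2, 100) to (0, targetL1, targetL2, 100); the map is monotone and
#' x is unchanged.
#'
#' @param ps a \linkS4class{ParameterizedSulcus} whose \code{L1}/\code{L2}
#'   are set (see \code{\link{detectLandmarks}}).
#' @param targetL1,targetL2 target landmark positions, 0 < targetL1 <
#'   targetL2 < 100.
#' @return A \linkS4class{ParameterizedSulcus} with stage "reparameterized".
#' @export
reparameterize <- function(ps, targetL1, targetL2) {
  L1 <- ps@L1; L2 <- ps@L2
  if (is.na(L1) || is.na(L2)) stop("subject landmarks are undefined")
  if (!(0 < L1 && L1 < L2 && L2 < 100))
    stop("subject landmarks must satisfy 0 < L1 < L2 < 100")
  if (!(0 < targetL1 && targetL1 < targetL2 && targetL2 < 100))
    stop("target landmarks must satisfy 0 < L1 < L2 < 100")
  ps@yField <- piecewiseLinearMap(ps@yField, c(0, L1, L2, 100),
                                  c(0, targetL1, targetL2, 100))
  ps@L1 <- targetL1
  ps@L2 <- targetL2
  ps@stage <- "reparameterized"
  ps
}

#' Build the template sulcus
#'
#' Generates the canonical correspondence target from a fixed
#' \linkS4class{SulcusSpec} and parameterizes it. The template stands in for
#' a population-average sulcus of the studied age range; its provenance
#' (spec seed) is recorded.
#'
#' @param spec the generating \linkS4class{SulcusSpec}.
#' @param P positions used to detect the template landmarks.
#' @return A \linkS4class{TemplateSulcus}.
#' @export
buildTemplate <- function(spec = sulcusSpec(), P = 100L) {
  ps <- parameterize(generateSulcus(spec))
  prof <- profileCurve(ps, P = P)
  lm <- detectLandmarks(prof)
  new("TemplateSulcus", ps,
      L1 = lm$L1 %||% NA_real_, L2 = lm$L2 %||% NA_real_,
      provenance = list(seed = spec@seed, length = spec@length,
                        generator = "sulcushape::generateSulcus"))
}

# 2-D barycentric coordinates of points `p` (n x 2) in triangle (a, b, c).
baryCoords2d <- function(p, a, b, c) {
  d <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  w1 <- ((b[2] - c[2]) * (p[, 1] - c[1]) + (c[1] - b[1]) * (p[, 2] - c[2])) / d
  w2 <- ((c[2] - a[2]) * (p[, 1] - c[1]) + (a[1] - c[1]) * (p[, 2] - c[2])) / d
  cbind(w1, w2, 1 - w1 - w2)
}

#' Resample subject fields onto the template nodes
#'
#' For each template node with parameters (x*, y*), interpolates the subject
#' field at (x*, y*) by barycentric interpolation in the subject's
#' parameter-space triangulation; template nodes falling outside the
#' subject's parameter domain take the value of the nearest subject node in
#' parameter space and are flagged. This yields the inter-subject
#' node-to-node correspondence used by the node-wise statistics.
#'
#' @param ps a \linkS4class{ParameterizedSulcus} (usually reparameterized).
#' @param template a \linkS4class{TemplateSulcus}.
#' @param fields named list of per-vertex numeric fields on \code{ps}.
#' @return Named list of numeric vectors on the template nodes, with
#'   attribute \code{outOfDomain} (indices of flagged template nodes).
#' @export
resampleToTemplate <- function(ps, template, fields) {
  stopifnot(is.list(fields), length(fields) > 0L)
  nSub <- nrow(ps@mesh@vertices)
  for (f in fields) if (length(f) != nSub)
    stop("fields must have one value per subject vertex")
  Pxy <- cbind(xField(template), yField(template))
  nT <- nrow(Pxy)
  Sxy <- cbind(ps@xField, ps@yField)
  F <- ps@mesh@triangles
  triIdx <- rep(NA_integer_, nT)
  w <- matrix(NA_real_, nT, 3)
  ordY <- order(Pxy[, 2])
  ys <- Pxy[ordY, 2]
  tol <- 1e-9
  for (t in seq_len(nrow(F))) {
    tri <- F[t, ]
    a <- Sxy[tri[1], ]; b <- Sxy[tri[2], ]; c <- Sxy[tri[3], ]
    ylo <- min(a[2], b[2], c[2]) - tol; yhi <- max(a[2], b[2], c[2]) + tol
    lo <- findInterval(ylo, ys) + 1L
    hi <- findInterval(yhi, ys)
    if (hi < lo) next
    cand <- ordY[lo:hi]
    cand <- cand[is.na(triIdx[cand])]
    if (!length(cand)) next
    xlo <- min(a[1], b[1], c[1]) - tol; xhi <- max(a[1], b[1], c[1]) + tol
    cand <- cand[Pxy[cand, 1] >= xlo & Pxy[cand, 1] <= xhi]
    if (!length(cand)) next
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    if (abs(det) < 1e-14) next
    bw <- baryCoords2d(Pxy[cand, , drop = FALSE], a, b, c)
    inside <- rowSums(bw >= -1e-9) == 3L
    if (any(inside)) {
      sel <- cand[inside]
      triIdx[sel] <- t
      w[sel, ] <- bw[inside, , drop = FALSE]
    }
  }
  out <- which(is.na(triIdx))
  nearest <- integer(0)
  if (length(out)) {
    nearest <- vapply(out, function(i) {
      which.min((Sxy[, 1] - Pxy[i, 1])^2 + (Sxy[, 2] - Pxy[i, 2])^2)
    }, integer(1))
  }
  res <- lapply(fields, function(f) {
    vals <- numeric(nT)
    ok <- !is.na(triIdx)
    tri <- F[triIdx[ok], , drop = FALSE]
    vals[ok] <- w[ok, 1] * f[tri[, 1]] + w[ok, 2] * f[tri[, 2]] +
      w[ok, 3] * f[tri[, 3]]
    if (length(out)) vals[out] <- f[nearest]
    vals
  })
  attr(res, "outOfDomain") <- out
  res
}
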