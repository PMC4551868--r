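#' @import methods
#' @importFrom stats approx rnorm runif rbinom sd pt setNames quantile p.adjust
#' @importFrom utils read.csv write.csv modifyList packageVersion
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SulcalMesh: a labeled sulcal ribbon mesh
#'
#' A triangle mesh of one sulcus (the medial surface between two opposing
#' gyral banks) together with the anatomical labels the downstream analysis
#' needs: the top ridge (intersection with the brain envelope), the bottom
#' ridge (fundus), and the superior/inferior endpoints.
#'
#' Two boundary topologies are accepted:
#' \itemize{
#'   \item \emph{closed}: the two ridge paths share their terminal vertices,
#'     which are the endpoints (a sulcus tapering to a point at each end);
#'   \item \emph{open}: the ridges are disjoint and the boundary is closed by
#'     two "end walls"; the endpoints are then the ridge termini on the top
#'     ridge.
#' }
#'
#' @slot vertices numeric matrix, N x 3, coordinates in mm.
#' @slot triangles integer matrix, M x 3, 1-based vertex indices.
#' @slot topRidge integer vector, ordered vertex path along the brain-envelope
#'   edge (superior to inferior).
#' @slot bottomRidge integer vector, ordered vertex path along the fundus.
#' @slot endpointSuperior,endpointInferior integer(1), endpoint vertex ids.
#' @slot companions named list of companion surfaces (\code{bankAnterior},
#'   \code{bankPosterior}, \code{interfaceInner}, \code{interfaceOuter}), each
#'   a list with elements \code{vertices} and \code{triangles}.
#' @slot nodeFields named list of per-vertex numeric fields (e.g.
#'   \code{thickness} in mm).
#' @slot meta list of free-form metadata (subject id, hemisphere, group,
#'   generator ground truth, ...).
#' @exportClass SulcalMesh
setClass("SulcalMesh",
  representation(
    vertices = "matrix",
    triangles = "matrix",
    topRidge = "integer",
    bottomRidge = "integer",
    endpointSuperior = "integer",
    endpointInferior = "integer",
    companions = "list",
    nodeFields = "list",
    meta = "list"
  ),
  prototype(vertices = matrix(numeric(0), 0, 3),
            triangles = matrix(integer(0), 0, 3),
            topRidge = integer(0), bottomRidge = integer(0),
            endpointSuperior = integer(0), endpointInferior = integer(0),
            companions = list(), nodeFields = list(), meta = list())
)

setValidity("SulcalMesh", function(object) {
  msg <- character(0)
  V <- object@vertices
  F <- object@triangles
  if (nrow(V) == 0L && nrow(F) == 0L) return(TRUE)  # empty placeholder
  if (!is.numeric(V) || ncol(V) != 3) msg <- c(msg, "vertices must be an N x 3 numeric matrix")
  if (ncol(F) != 3) msg <- c(msg, "triangles must be an M x 3 index matrix")
  n <- nrow(V)
  if (length(msg) == 0L) {
    if (any(F < 1L) || any(F > n)) msg <- c(msg, "triangle indices out of range")
  }
  if (length(msg) == 0L) {
    ar <- triangleAreas(V, F)
    if (any(ar <= 0)) msg <- c(msg, sprintf("%d degenerate (zero-area) triangles", sum(ar <= 0)))
    ec <- edgeUseCounts(F)
    if (any(ec$count > 2L)) msg <- c(msg, "mesh is not edge-manifold (an edge borders >2 triangles)")
    if (nComponents(F, n) != 1L) msg <- c(msg, "mesh has more than one connected component")
    bset <- boundaryVertexSet(F)
    tr <- object@topRidge; br <- object@bottomRidge
    es <- object@endpointSuperior; ei <- object@endpointInferior
    if (length(tr) < 2L || length(br) < 2L) msg <- c(msg, "ridge paths need at least 2 vertices")
    if (!all(c(tr, br) %in% bset)) msg <- c(msg, "all ridge vertices must lie on the mesh boundary")
    shared <- intersect(tr, br)
    if (length(setdiff(shared, c(es, ei))) > 0L)
      msg <- c(msg, "top and bottom ridges share a non-endpoint vertex")
    if (!(es %in% c(tr[1L], tr[length(tr)])))
      msg <- c(msg, "endpointSuperior must terminate the top ridge")
    if (!(ei %in% c(tr[1L], tr[length(tr)])))
      msg <- c(msg, "endpointInferior must terminate the top ridge")
    if (identical(es, ei)) msg <- c(msg, "endpoints must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SulcalMesh
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param triangles M x 3 matrix of 1-based vertex indices.
#' @param topRidge,bottomRidge ordered integer vertex paths.
#' @param endpointSuperior,endpointInferior endpoint vertex indices.
#' @param companions named list of companion surfaces.
#' @param nodeFields named list of per-vertex numeric fields.
#' @param meta metadata list.
#' @param validate run the validity checks (default TRUE).
#' @return A \linkS4class{SulcalMesh}.
#' @export
SulcalMesh <- function(vertices, triangles, topRidge, bottomRidge,
                       endpointSuperior, endpointInferior,
                       companions = list(), nodeFields = list(), meta = list(),
                       validate = TRUE) {
  V <- as.matrix(vertices)
  dimnames(V) <- NULL
  F <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  # slots are filled after construction so that validate = FALSE can carry
  # intentionally dirty meshes (pre-pruning input with fins, etc.)
  obj <- new("SulcalMesh")
  obj@vertices <- V
  obj@triangles <- F
  obj@topRidge <- as.integer(topRidge)
  obj@bottomRidge <- as.integer(bottomRidge)
  obj@endpointSuperior <- as.integer(endpointSuperior)
  obj@endpointInferior <- as.integer(endpointInferior)
  obj@companions <- companions
  obj@nodeFields <- nodeFields
  obj@meta <- meta
  if (validate) validObject(obj)
  obj
}

#' ParameterizedSulcus: a sulcal mesh with (x, y) coordinate fields
#'
#' Carries the two harmonic coordinate fields on a \linkS4class{SulcalMesh}:
#' \code{x} runs from the top ridge (0, brain envelope) to the bottom ridge
#' (100, fundus); \code{y} runs from the superior endpoint (0) to the inferior
#' endpoint (100). Landmarks L1/L2 are y positions on the sulcal profile.
#'
#' @slot mesh the underlying \linkS4class{SulcalMesh}.
#' @slot xField,yField per-vertex coordinates in [0, 100].
#' @slot L1,L2 landmark y positions (NA until detected/undefined).
#' @slot stage one of "raw", "reparameterized", "template_resampled".
#' @exportClass ParameterizedSulcus
setClass("ParameterizedSulcus",
  representation(
    mesh = "SulcalMesh",
    xField = "numeric",
    yField = "numeric",
    L1 = "numeric",
    L2 = "numeric",
    stage = "character"
  ),
  prototype(L1 = NA_real_, L2 = NA_real_, stage = "raw")
)

setValidity("ParameterizedSulcus", function(object) {
  msg <- character(0)
  n <- nrow(object@mesh@vertices)
  if (length(object@xField) != n || length(object@yField) != n)
    msg <- c(msg, "coordinate fields must have one value per vertex")
  tol <- 1e-6
  if (length(object@xField) == n) {
    if (any(object@xField < -tol) || any(object@xField > 100 + tol))
      msg <- c(msg, "xField outside [0, 100]")
    if (any(object@yField < -tol) || any(object@yField > 100 + tol))
      msg <- c(msg, "yField outside [0, 100]")
  }
  if (!object@stage %in% c("raw", "reparameterized", "template_resampled"))
    msg <- c(msg, "unknown stage")
  if (!is.na(object@L1) && !is.na(object@L2) && !(object@L1 < object@L2))
    msg <- c(msg, "L1 must be smaller than L2")
  if (length(msg)) msg else TRUE
})

#' TemplateSulcus: the correspondence target
#'
#' A canonical parameterized sulcus with a fixed node set, used as the target
#' of inter-subject node-to-node correspondence. \code{provenance} records how
#' it was built (generator spec and seed).
#'
#' @slot provenance list describing the template's origin.
#' @exportClass TemplateSulcus
setClass("TemplateSulcus", contains = "ParameterizedSulcus",
  representation(provenance = "list"), prototype(provenance = list()))

#' InertialPlane: barycenter + principal axes of a sulcal mesh
#'
#' @slot barycenter numeric(3), vertex barycenter (mm).
#' @slot axes 3 x 3 matrix; columns u1, u2, u3 are the eigenvectors of the
#'   vertex covariance by decreasing eigenvalue. u1, u2 span the inertial
#'   plane; u3 is its normal.
#' @slot eigenvalues numeric(3), decreasing (mm^2).
#' @exportClass InertialPlane
setClass("InertialPlane",
  representation(barycenter = "numeric", axes = "matrix", eigenvalues = "numeric"))

setValidity("InertialPlane", function(object) {
  msg <- character(0)
  if (length(object@barycenter) != 3) msg <- c(msg, "barycenter must be length 3")
  if (!all(dim(object@axes) == c(3, 3))) msg <- c(msg, "axes must be 3 x 3")
  else if (max(abs(crossprod(object@axes) - diag(3))) > 1e-9)
    msg <- c(msg, "axes must be orthonormal")
  if (is.unsorted(rev(object@eigenvalues))) msg <- c(msg, "eigenvalues must be decreasing")
  if (length(msg)) msg else TRUE
})

#' ProfileCurve: the sulcal profile
#'
#' Mean signed distance of mesh nodes to the inertial plane, as a function of
#' the y position (positions p = 1..P map to y = p * 100 / P).
#'
#' @slot positions integer 1..P.
#' @slot values mean signed distance per position (mm).
#' @slot nodeDistances per-node signed distances d_i (mm).
#' @slot counts number of nodes per bin.
#' @slot interpolated logical; TRUE where an empty bin was filled in.
#' @exportClass ProfileCurve
setClass("ProfileCurve",
  representation(positions = "integer", values = "numeric",
    nodeDistances = "numeric", counts = "integer", interpolated = "logical"))

#' DepthPositionProfile: sulcal depth along y
#'
#' @slot positions integer 1..P.
#' @slot depth depth per position (mm).
#' @slot mode "geodesic" (isoparameter arclength across the ribbon) or
#'   "euclidean" (straight-line fundus-to-envelope distance).
#' @slot flagged logical; TRUE where the position had no level-set support and
#'   took the nearest supported value.
#' @exportClass DepthPositionProfile
setClass("DepthPositionProfile",
  representation(positions = "integer", depth = "numeric", mode = "character",
    flagged = "logical"))

setValidity("DepthPositionProfile", function(object) {
  if (!object@mode %in% c("geodesic", "euclidean")) return("unknown depth mode")
  if (any(object@depth <= 0)) return("depth must be positive at supported positions")
  TRUE
})

#' GlobalMetrics: the six global shape measures of one sulcus
#'
#' @slot averageLength mean arclength of the two ridge boundaries (mm).
#' @slot averageDepth,maxDepth mean/max of the depth-position profile (mm).
#' @slot averageSpan mean bank-to-bank distance along medial normals (mm).
#' @slot averageThickness mean cortical thickness along the sulcus (mm).
#' @slot surfaceArea total triangle area (mm^2).
#' @exportClass GlobalMetrics
setClass("GlobalMetrics",
  representation(averageLength = "numeric", averageDepth = "numeric",
    maxDepth = "numeric", averageSpan = "numericOrNULL",
    averageThickness = "numericOrNULL", surfaceArea = "numeric"))

setValidity("GlobalMetrics", function(object) {
  msg <- character(0)
  if (object@maxDepth < object@averageDepth - 1e-9)
    msg <- c(msg, "maxDepth must be >= averageDepth")
  vals <- c(object@averageLength, object@averageDepth, object@maxDepth,
            object@averageSpan, object@averageThickness, object@surfaceArea)
  if (any(vals < 0)) msg <- c(msg, "metrics must be non-negative")
  if (length(msg)) msg else TRUE
})

#' StatMap: per-unit group/association statistics
#'
#' One row per tested unit (a global metric, a y position, or a template
#' node): effect estimate, t, two-sided p, BH-adjusted q and the significance
#' call at level alpha.
#'
#' @slot unit "global", "position" or "node".
#' @slot ids unit identifiers.
#' @slot beta,t,p,q numeric vectors, one value per unit (NA for degenerate
#'   units excluded from FDR).
#' @slot significant logical; q <= alpha.
#' @slot alpha the significance level used.
#' @slot df residual degrees of freedom of the adjusted model.
#' @slot extra list (e.g. significant y intervals for position maps).
#' @exportClass StatMap
setClass("StatMap",
  representation(unit = "character", ids = "character", beta = "numeric",
    t = "numeric", p = "numeric", q = "numeric", significant = "logical",
    alpha = "numeric", df = "numeric", extra = "list"),
  prototype(extra = list()))

setValidity("StatMap", function(object) {
  msg <- character(0)
  lens <- c(length(object@ids), length(object@beta), length(object@t),
            length(object@p), length(object@q), length(object@significant))
  if (length(unique(lens)) != 1L) msg <- c(msg, "all per-unit vectors must have equal length")
  ok <- !is.na(object@p) & !is.na(object@q)
  if (any(object@q[ok] < object@p[ok] - 1e-12)) msg <- c(msg, "q must be >= p")
  if (any(object@significant[ok] != (object@q[ok] <= object@alpha)))
    msg <- c(msg, "significant must equal q <= alpha")
  if (length(msg)) msg else TRUE
})

#' SulcusSpec: parameters of one synthetic sulcus
#'
#' Describes a folded-ribbon sulcal mesh: a centerline of a given length along
#' the superior-inferior axis, displaced laterally by \code{profileFn}, with
#' the ribbon extending from the top ridge down to a fundus at depth
#' \code{depthFn(y)}. All functions take y in [0, 100].
#'
#' @slot length sulcus length (mm).
#' @slot depthFn function y -> depth (mm), positive on [0, 100].
#' @slot profileFn function y -> lateral displacement (mm).
#' @slot span bank-to-bank distance (mm).
#' @slot thicknessFn function y -> cortical thickness (mm).
#' @slot meshResolution target edge length, scalar or c(along, depth) (mm).
#' @slot seed integer RNG seed.
#' @slot noiseSd vertex jitter SD (mm).
#' @exportClass SulcusSpec
setClass("SulcusSpec",
  representation(length = "numeric", depthFn = "function", profileFn = "function",
    span = "numeric", thicknessFn = "function", meshResolution = "numeric",
    seed = "integer", noiseSd = "numeric"))

setValidity("SulcusSpec", function(object) {
  msg <- character(0)
  if (object@length <= 0) msg <- c(msg, "length must be positive")
  y <- seq(0, 100, length.out = 201)
  if (any(object@depthFn(y) <= 0)) msg <- c(msg, "depthFn must be positive on [0, 100]")
  if (any(object@meshResolution <= 0)) msg <- c(msg, "meshResolution must be positive")
  if (!length(object@meshResolution) %in% 1:2) msg <- c(msg, "meshResolution must have length 1 or 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of a synthetic two-group cohort
#'
#' @slot nPerGroup subjects per group (>= 2).
#' @slot base the base \linkS4class{SulcusSpec} all subjects perturb.
#' @slot groupEffects list of effects, each a list with \code{target}
#'   ("depth", "profile", "thickness", "span", "length"), \code{amplitude}
#'   (mm), optional \code{window} = c(lo, hi) in y units (global when NULL)
#'   and \code{group} (default "case").
#' @slot subjectVariation list of between-subject SDs: \code{depthOffset}
#'   (scalar or c(case, control)), \code{depthSmooth}, \code{profileSmooth},
#'   \code{thickness} (scalar or per group), \code{span}, \code{length},
#'   \code{nModes} (Fourier modes of the smooth perturbations).
#' @slot covariateModel list: \code{ageMean}, \code{ageSd}, \code{pBoy}
#'   (per group), and \code{slopes} (e.g. \code{depthAge} in mm/month).
#' @slot scoreModel list: per-score \code{mean}/\code{sd} per group, and
#'   \code{coupling} (list with \code{score}, \code{window}, \code{coeff} in
#'   score units per mm of window-mean profile deviation).
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nPerGroup = "integer", base = "SulcusSpec",
    groupEffects = "list", subjectVariation = "list", covariateModel = "list",
    scoreModel = "list", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  for (eff in object@groupEffects) {
    if (!is.null(eff$window)) {
      if (length(eff$window) != 2L || eff$window[1] < 0 || eff$window[2] > 100 ||
          eff$window[1] >= eff$window[2])
        msg <- c(msg, "effect windows must be increasing sub-intervals of [0, 100]")
    }
  }
  sm <- object@scoreModel
  for (nm in setdiff(names(sm), "coupling"))
    if (any(unlist(sm[[nm]][c("sd")]) < 0)) msg <- c(msg, "score SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SulcalCohort: a generated cohort with ground truth
#'
#' @slot meshes list of \linkS4class{SulcalMesh}, one per subject.
#' @slot table the cohort data.frame (subject_id, group, age_months, gender,
#'   clinical scores).
#' @slot groundTruth list: the generating \linkS4class{CohortSpec} plus the
#'   realized per-subject truth (mean depth, profile curves, ...).
#' @exportClass SulcalCohort
setClass("SulcalCohort",
  representation(meshes = "list", table = "data.frame", groundTruth = "list"))
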