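#' @name accessors
#' @title Accessors for sulcushape objects
#' @description Slot accessors for \linkS4class{SulcalMesh},
#'   \linkS4class{ParameterizedSulcus}, \linkS4class{SulcalCohort} and
#'   friends. Use these instead of \code{@}.
#' @param object a sulcushape object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("triangles", function(object) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setGeneric("topRidge", function(object) standardGeneric("topRidge"))
#' @rdname accessors
#' @export
setGeneric("bottomRidge", function(object) standardGeneric("bottomRidge"))
#' @rdname accessors
#' @export
setGeneric("endpoints", function(object) standardGeneric("endpoints"))
#' @rdname accessors
#' @export
setGeneric("companions", function(object) standardGeneric("companions"))
#' @rdname accessors
#' @export
setGeneric("nodeFields", function(object) standardGeneric("nodeFields"))
#' @rdname accessors
#' @export
setGeneric("meshMeta", function(object) standardGeneric("meshMeta"))
#' @rdname accessors
#' @export
setGeneric("xField", function(object) standardGeneric("xField"))
#' @rdname accessors
#' @export
setGeneric("yField", function(object) standardGeneric("yField"))
#' @rdname accessors
#' @export
setGeneric("landmarks", function(object) standardGeneric("landmarks"))
#' @rdname accessors
#' @export
setGeneric("parameterStage", function(object) standardGeneric("parameterStage"))
#' @rdname accessors
#' @export
setGeneric("meshes", function(object) standardGeneric("meshes"))
#' @rdname accessors
#' @export
setGeneric("cohortTable", function(object) standardGeneric("cohortTable"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("depthValues", function(object) standardGeneric("depthValues"))

setMethod("vertices", "SulcalMesh", function(object) object@vertices)
setMethod("triangles", "SulcalMesh", function(object) object@triangles)
setMethod("topRidge", "SulcalMesh", function(object) object@topRidge)
setMethod("bottomRidge", "SulcalMesh", function(object) object@bottomRidge)
setMethod("endpoints", "SulcalMesh", function(object)
  c(superior = object@endpointSuperior, inferior = object@endpointInferior))
setMethod("companions", "SulcalMesh", function(object) object@companions)
setMethod("nodeFields", "SulcalMesh", function(object) object@nodeFields)
setMethod("meshMeta", "SulcalMesh", function(object) object@meta)

setMethod("vertices", "ParameterizedSulcus", function(object) object@mesh@vertices)
setMethod("triangles", "ParameterizedSulcus", function(object) object@mesh@triangles)
setMethod("topRidge", "ParameterizedSulcus", function(object) object@mesh@topRidge)
setMethod("bottomRidge", "ParameterizedSulcus", function(object) object@mesh@bottomRidge)
setMethod("endpoints", "ParameterizedSulcus", function(object) endpoints(object@mesh))
setMethod("companions", "ParameterizedSulcus", function(object) object@mesh@companions)
setMethod("nodeFields", "ParameterizedSulcus", function(object) object@mesh@nodeFields)
setMethod("meshMeta", "ParameterizedSulcus", function(object) object@mesh@meta)
setMethod("xField", "ParameterizedSulcus", function(object) object@xField)
setMethod("yField", "ParameterizedSulcus", function(object) object@yField)
setMethod("landmarks", "ParameterizedSulcus", function(object)
  c(L1 = object@L1, L2 = object@L2))
setMethod("parameterStage", "ParameterizedSulcus", function(object) object@stage)

setMethod("meshes", "SulcalCohort", function(object) object@meshes)
setMethod("cohortTable", "SulcalCohort", function(object) object@table)
setMethod("groundTruth", "SulcalCohort", function(object) object@groundTruth)
setMethod("groundTruth", "SulcalMesh", function(object) object@meta$groundTruth)

setMethod("profileValues", "ProfileCurve", function(object) object@values)
setMethod("depthValues", "DepthPositionProfile", function(object) object@depth)

#' @name morphometry-generics
#' @title Generics for sulcal shape measurements
#' @description Generic definitions for the morphometry operations; see
#'   the methods for \linkS4class{SulcalMesh} and
#'   \linkS4class{ParameterizedSulcus}.
#' @param object,mesh a \linkS4class{SulcalMesh} or
#'   \linkS4class{ParameterizedSulcus}.
#' @param ... passed to methods.
#' @return See the individual methods.
NULL

#' @rdname morphometry-generics
#' @export
setGeneric("surfaceArea", function(object) standardGeneric("surfaceArea"))
#' @rdname morphometry-generics
#' @export
setGeneric("sulcalLength", function(object) standardGeneric("sulcalLength"))
#' @rdname morphometry-generics
#' @export
setGeneric("sulcalSpan", function(object, ...) standardGeneric("sulcalSpan"))
#' @rdname morphometry-generics
#' @export
setGeneric("corticalThickness", function(object, ...) standardGeneric("corticalThickness"))
#' @rdname morphometry-generics
#' @export
setGeneric("inertialPlane", function(object, ...) standardGeneric("inertialPlane"))
#' @rdname morphometry-generics
#' @export
setGeneric("parameterize", function(mesh, ...) standardGeneric("parameterize"))

setMethod("show", "SulcalMesh", function(object) {
  cat(sprintf("SulcalMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
  cat(sprintf("  top ridge: %d vertices | bottom ridge: %d vertices\n",
              length(object@topRidge), length(object@bottomRidge)))
  if (length(object@companions))
    cat("  companions:", paste(names(object@companions), collapse = ", "), "\n")
  if (length(object@nodeFields))
    cat("  node fields:", paste(names(object@nodeFields), collapse = ", "), "\n")
  if (!is.null(object@meta$subject_id))
    cat(sprintf("  subject: %s (%s)\n", object@meta$subject_id,
                paste0(object@meta$hemisphere %||% "", " ", object@meta$group %||% "")))
})

setMethod("show", "ParameterizedSulcus", function(object) {
  cat(sprintf("ParameterizedSulcus [%s]: %d vertices\n", object@stage,
              nrow(object@mesh@vertices)))
  cat(sprintf("  x in [%.2f, %.2f], y in [%.2f, %.2f]\n",
              min(object@xField), max(object@xField),
              min(object@yField), max(object@yField)))
  if (!is.na(object@L1))
    cat(sprintf("  landmarks: L1 = %.1f, L2 = %.1f\n", object@L1, object@L2))
})

setMethod("show", "InertialPlane", function(object) {
  cat("InertialPlane\n  barycenter:", sprintf("%.3f", object@barycenter), "\n")
  cat("  eigenvalues:", sprintf("%.3g", object@eigenvalues), "\n")
  cat("  normal u3:", sprintf("%.4f", object@axes[, 3]), "\n")
})

setMethod("show", "GlobalMetrics", function(object) {
  df <- as.data.frame(object)
  cat("GlobalMetrics (mm / mm^2):\n")
  print(df, row.names = FALSE)
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap [%s]: %d units, alpha = %g, df = %g\n", object@unit,
              length(object@ids), object@alpha, object@df))
  cat(sprintf("  significant: %d (q <= alpha)\n", sum(object@significant, na.rm = TRUE)))
  if (!is.null(object@extra$intervals) && nrow(object@extra$intervals))
    cat("  intervals:", paste(sprintf("%d<=y<=%d", object@extra$intervals$start,
        object@extra$intervals$end), collapse = ", "), "\n")
})

setMethod("show", "SulcalCohort", function(object) {
  tab <- table(object@table$group)
  cat(sprintf("SulcalCohort: %d subjects (%s)\n", nrow(object@table),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
})

#' @export
as.data.frame.GlobalMetrics <- function(x, ...) {
  data.frame(average_length = x@averageLength, average_depth = x@averageDepth,
    max_depth = x@maxDepth,
    average_span = if (is.null(x@averageSpan)) NA_real_ else x@averageSpan,
    average_thickness = if (is.null(x@averageThickness)) NA_real_ else x@averageThickness,
    surface_area = x@surfaceArea)
}

#' @export
as.data.frame.StatMap <- function(x, ...) {
  data.frame(id = x@ids, beta = x@beta, t = x@t, p = x@p, q = x@q,
             significant = x@significant, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
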