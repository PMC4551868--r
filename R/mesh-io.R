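# Reading/writing labeled sulcal meshes (OFF, PLY, minimal ASCII GIFTI) with a
# JSON sidecar carrying the ridge/endpoint labels, per-vertex fields and
# metadata, plus the automated analog of manual accessory-fold removal.
#
# There is no standard sulcal-label convention in any mesh format, so labels
# always travel in the sidecar; the loader refuses to guess.

formatFromPath <- function(path) {
  if (grepl("\\.gii$", path, ignore.case = TRUE)) return("gifti")
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return("ply")
  if (grepl("\\.off$", path, ignore.case = TRUE)) return("off")
  stop("cannot infer mesh format from extension of '", path,
       "'; pass format explicitly")
}

defaultSidecar <- function(path) paste0(path, ".labels.json")

fmtNum <- function(x) formatC(x, format = "g", digits = 12)

writeOff <- function(V, F, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(V), nrow(F)), con)
  writeLines(paste(fmtNum(V[, 1]), fmtNum(V[, 2]), fmtNum(V[, 3])), con)
  writeLines(paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

readOff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  n <- counts[1]; m <- counts[2]
  V <- matrix(scan(text = lines[3:(2 + n)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[(3 + n):(2 + n + m)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle faces are supported")
  list(vertices = V, triangles = matrix(as.integer(fl[, 2:4]) + 1L, ncol = 3))
}

writePly <- function(V, F, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(V)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(F)),
    "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(fmtNum(V[, 1]), fmtNum(V[, 2]), fmtNum(V[, 3])), con)
  writeLines(paste(3L, F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

readPly <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  if (is.na(endh)) stop("not an ascii PLY file: ", path)
  header <- lines[1:endh]
  if (!any(grepl("format ascii", header))) stop("only ascii PLY is supported")
  n <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  m <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  body <- lines[-(1:endh)]
  V <- matrix(scan(text = body[1:n], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = body[(n + 1):(n + m)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle faces are supported")
  list(vertices = V, triangles = matrix(as.integer(fl[, 2:4]) + 1L, ncol = 3))
}

giftiDataArray <- function(parent, intent, type, dat, dims) {
  da <- xml2::xml_add_child(parent, "DataArray",
    Intent = intent, DataType = type, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)), Encoding = "ASCII",
    Endian = "LittleEndian", ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims)) xml2::xml_set_attr(da, paste0("Dim", i - 1L), dims[i])
  xml2::xml_add_child(da, "Data", paste(fmtNum(t(dat)), collapse = " "))
  invisible(da)
}

writeGifti <- function(V, F, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0", NumberOfDataArrays = "2")
  giftiDataArray(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64", V,
                 c(nrow(V), 3L))
  giftiDataArray(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", F - 1L,
                 c(nrow(F), 3L))
  xml2::write_xml(doc, path)
}

readGifti <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(das, "Intent")
  grab <- function(intent) {
    i <- which(intents == intent)
    if (!length(i)) stop("GIFTI file lacks a ", intent, " array: ", path)
    da <- das[[i[1]]]
    if (xml2::xml_attr(da, "Encoding") != "ASCII")
      stop("only ASCII-encoded GIFTI is supported")
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    matrix(vals, ncol = as.integer(xml2::xml_attr(da, "Dim1")), byrow = TRUE)
  }
  list(vertices = grab("NIFTI_INTENT_POINTSET"),
       triangles = matrix(as.integer(grab("NIFTI_INTENT_TRIANGLE")), ncol = 3) + 1L)
}

serializableMeta <- function(meta) {
  Filter(function(x) !is.function(x),
         rapply(meta, identity, classes = "ANY", how = "replace"))
}

#' Write a sulcal mesh with its label sidecar
#'
#' Writes the triangle mesh in OFF, ascii PLY or ascii GIFTI format and the
#' ridge/endpoint labels, per-vertex fields and metadata to a JSON sidecar
#' (\code{<path>.labels.json} by default). Companion surfaces are not
#' serialized.
#'
#' @param mesh a \linkS4class{SulcalMesh}.
#' @param path output file; the extension selects the format unless
#'   \code{format} is given.
#' @param format "auto", "off", "ply" or "gifti".
#' @param sidecar path of the JSON label sidecar.
#' @return \code{path}, invisibly.
#' @export
writeSulcalMesh <- function(mesh, path, format = c("auto", "off", "ply", "gifti"),
                            sidecar = defaultSidecar(path)) {
  format <- match.arg(format)
  if (format == "auto") format <- formatFromPath(path)
  V <- mesh@vertices; F <- mesh@triangles
  switch(format, off = writeOff(V, F, path), ply = writePly(V, F, path),
         gifti = writeGifti(V, F, path))
  lab <- list(
    top_ridge = mesh@topRidge, bottom_ridge = mesh@bottomRidge,
    endpoint_superior = mesh@endpointSuperior,
    endpoint_inferior = mesh@endpointInferior,
    vertex_label = vertexLabelField(mesh),
    node_fields = mesh@nodeFields,
    meta = serializableMeta(mesh@meta))
  jsonlite::write_json(lab, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Integer per-vertex label field: 0 interior, 1 top ridge, 2 bottom ridge,
# 3 endpoint (endpoints win over ridge membership).
vertexLabelField <- function(mesh) {
  lab <- integer(nrow(mesh@vertices))
  lab[mesh@topRidge] <- 1L
  lab[mesh@bottomRidge] <- 2L
  lab[c(mesh@endpointSuperior, mesh@endpointInferior)] <- 3L
  lab
}

#' Read a labeled sulcal mesh
#'
#' Reads a triangle mesh (OFF, ascii PLY or ascii GIFTI) plus its JSON label
#' sidecar and returns a validated \linkS4class{SulcalMesh}. Vertices are
#' never reordered. The function fails loudly when the sidecar is missing or
#' inconsistent with the mesh rather than guessing labels.
#'
#' @param path mesh file.
#' @param format "auto" (from the extension), "off", "ply" or "gifti".
#' @param sidecar path of the JSON label sidecar
#'   (default \code{<path>.labels.json}).
#' @param validate run the \linkS4class{SulcalMesh} validity checks.
#' @return A \linkS4class{SulcalMesh}.
#' @export
readSulcalMesh <- function(path, format = c("auto", "off", "ply", "gifti"),
                           sidecar = defaultSidecar(path), validate = TRUE) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") format <- formatFromPath(path)
  geo <- switch(format, off = readOff(path), ply = readPly(path),
                gifti = readGifti(path))
  if (!file.exists(sidecar))
    stop("label sidecar not found: ", sidecar,
         " (ridge/endpoint labels are required; they are never guessed)")
  lab <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("top_ridge", "bottom_ridge", "endpoint_superior", "endpoint_inferior")
  if (!all(need %in% names(lab)))
    stop("label sidecar lacks fields: ",
         paste(setdiff(need, names(lab)), collapse = ", "))
  nf <- lapply(lab$node_fields %||% list(), as.numeric)
  SulcalMesh(geo$vertices, geo$triangles,
    topRidge = lab$top_ridge, bottomRidge = lab$bottom_ridge,
    endpointSuperior = lab$endpoint_superior,
    endpointInferior = lab$endpoint_inferior,
    nodeFields = nf, meta = as.list(lab$meta %||% list()),
    validate = validate)
}

#' Remove accessory branches from a sulcal mesh
#'
#' Automated analog of the manual pruning of small accessory folds: connected
#' components other than the largest-area sheet are removed, and side-branch
#' fins attached to the sheet through non-manifold junction edges are removed
#' when their maximal extent from the junction is below
#' \code{lengthThreshold} (default 5 mm, the conventional size of random
#' accessory folds). The main sheet is never modified, and the operation is
#' idempotent. Vertex order of the retained vertices is preserved.
#'
#' @param mesh a \linkS4class{SulcalMesh}; may be non-manifold or
#'   multi-component (build with \code{validate = FALSE}).
#' @param lengthThreshold fin extent threshold (mm).
#' @return A validated \linkS4class{SulcalMesh}.
#' @export
removeAccessoryBranches <- function(mesh, lengthThreshold = 5) {
  V <- mesh@vertices; F <- mesh@triangles
  ec <- edgeUseCounts(F)
  junctionKeys <- ec$key[!duplicated(ec$key)][ec$count >= 3L]
  # face adjacency through ordinary (2-face, non-junction) edges
  keyAll <- ec$key                       # 3M keys, face-major blocks
  faceOfKey <- rep(seq_len(nrow(F)), 3L)
  ord <- order(keyAll)
  keyS <- keyAll[ord]; faceS <- faceOfKey[ord]
  runStart <- which(!duplicated(keyS))
  runEnd <- c(runStart[-1] - 1L, length(keyS))
  pairs <- NULL
  two <- which(runEnd - runStart == 1L & !(keyS[runStart] %in% junctionKeys))
  if (length(two))
    pairs <- cbind(faceS[runStart[two]], faceS[runEnd[two]])
  else pairs <- matrix(integer(0), 0, 2)
  comp <- unionFind(nrow(F), pairs)
  areas <- triangleAreas(V, F)
  compArea <- tapply(areas, comp, sum)
  mainComp <- as.integer(names(compArea)[which.max(compArea)])
  mainFaces <- which(comp == mainComp)
  mainKeys <- unique(as.vector(ec$faceEdgeKeys[mainFaces, ]))
  keep <- rep(FALSE, nrow(F))
  keep[mainFaces] <- TRUE
  for (cc in setdiff(unique(comp), mainComp)) {
    faces <- which(comp == cc)
    keys <- unique(as.vector(ec$faceEdgeKeys[faces, ]))
    attachKeys <- intersect(intersect(keys, junctionKeys), mainKeys)
    if (!length(attachKeys)) next  # disconnected flap: always removed
    jverts <- unique(as.integer(unlist(strsplit(attachKeys, " "))))
    cverts <- unique(as.vector(F[faces, ]))
    d2 <- vapply(cverts, function(v)
      min(colSums((t(V[jverts, , drop = FALSE]) - V[v, ])^2)), numeric(1))
    extent <- sqrt(max(d2))
    if (extent >= lengthThreshold) keep[faces] <- TRUE  # large branch retained
  }
  if (all(keep)) return(mesh)
  subsetMeshFaces(mesh, which(keep))
}

# Restrict a mesh to a face subset, dropping unreferenced vertices while
# preserving the relative order of the kept vertices.
subsetMeshFaces <- function(mesh, faceIdx) {
  F <- mesh@triangles[faceIdx, , drop = FALSE]
  dimnames(F) <- NULL
  kept <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh@vertices))
  remap[kept] <- seq_along(kept)
  ridgeMap <- function(idx) {
    idx <- idx[idx %in% kept]
    remap[idx]
  }
  SulcalMesh(mesh@vertices[kept, , drop = FALSE],
    matrix(remap[F], ncol = 3),
    topRidge = ridgeMap(mesh@topRidge), bottomRidge = ridgeMap(mesh@bottomRidge),
    endpointSuperior = remap[mesh@endpointSuperior],
    endpointInferior = remap[mesh@endpointInferior],
    companions = mesh@companions,
    nodeFields = lapply(mesh@nodeFields, function(f) f[kept]),
    meta = mesh@meta)
}

cohortColumns <- c("subject_id", "group", "age_months", "gender",
  "inattention", "hyperactivity_impulsivity", "dsm_total")

#' Validate a cohort table
#'
#' Checks the demographic/clinical table used by the group statistics:
#' required columns present, unique subject ids, exactly two group levels,
#' and no missing covariates or scores.
#'
#' @param df a data.frame.
#' @return \code{df}, with \code{group} as character, invisibly usable.
#' @export
validateCohortTable <- function(df) {
  missingCols <- setdiff(cohortColumns, names(df))
  if (length(missingCols))
    stop("cohort table lacks columns: ", paste(missingCols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  df$group <- as.character(df$group)
  lv <- unique(df$group)
  if (length(lv) != 2L)
    stop("group must have exactly two levels, found: ", paste(lv, collapse = ", "))
  numCols <- setdiff(cohortColumns, c("subject_id", "group"))
  for (cl in numCols) {
    df[[cl]] <- as.numeric(df[[cl]])
    if (anyNA(df[[cl]]))
      stop("missing ", cl, " for subject(s): ",
           paste(df$subject_id[is.na(df[[cl]])], collapse = ", "))
  }
  df
}

#' Read a cohort table (CSV/TSV)
#'
#' @param path a CSV or TSV file with a header row and columns
#'   \code{subject_id}, \code{group}, \code{age_months}, \code{gender},
#'   \code{inattention}, \code{hyperactivity_impulsivity}, \code{dsm_total}.
#' @return A validated data.frame.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validateCohortTable(df)
}
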