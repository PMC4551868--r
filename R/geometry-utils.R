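# Low-level triangle-mesh helpers shared across modules. Vertices are N x 3
# matrices in mm; triangles are M x 3 matrices of 1-based indices.

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowNorms <- function(m) sqrt(rowSums(m * m))

triangleAreas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  0.5 * rowNorms(rowCross(e1, e2))
}

# All (undirected) edges with the number of triangles using each.
edgeUseCounts <- function(F) {
  ea <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  tab <- table(key)
  u <- !duplicated(key)
  cnt <- as.integer(tab[key[u]])
  list(edges = cbind(pmin(ea[u, 1], ea[u, 2]), pmax(ea[u, 1], ea[u, 2])),
       count = cnt, key = key, faceEdgeKeys = matrix(key, ncol = 3))
}

boundaryEdges <- function(F) {
  ec <- edgeUseCounts(F)
  ec$edges[ec$count == 1L, , drop = FALSE]
}

boundaryVertexSet <- function(F) unique(as.vector(boundaryEdges(F)))

# Union-find over vertices joined by triangle edges.
unionFind <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

nComponents <- function(F, n) {
  used <- sort(unique(as.vector(F)))
  ec <- edgeUseCounts(F)
  comp <- unionFind(n, ec$edges)
  length(unique(comp[used]))
}

# Area-weighted vertex normals.
vertexNormals <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- rowCross(e1, e2)  # length = 2 * area
  N <- matrix(0, nrow(V), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], F[, j])
      N[as.integer(rownames(acc)), d] <- N[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- rowNorms(N)
  len[len == 0] <- 1
  N / len
}

polylineLength <- function(V, idx) {
  if (length(idx) < 2L) return(0)
  seg <- V[idx[-1L], , drop = FALSE] - V[idx[-length(idx)], , drop = FALSE]
  sum(rowNorms(seg))
}

# Signed parameters t of the intersections of the line p + t * dir with the
# triangles of (V, F); returns the t of the hit nearest to p, or NA.
lineMeshIntersect <- function(p, dir, V, F) {
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  dirm <- matrix(dir, nrow(F), 3, byrow = TRUE)
  pvec <- rowCross(dirm, e2)
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- matrix(p, nrow(F), 3, byrow = TRUE) - v0
  u <- rowSums(tvec * pvec) / det
  qvec <- rowCross(tvec, e1)
  v <- rowSums(qvec * dirm) / det
  tt <- rowSums(e2 * qvec) / det
  hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9
  if (!any(hit)) return(NA_real_)
  th <- tt[hit]
  th[which.min(abs(th))]
}

# Continuous piecewise-linear map through the given (x, y) knots.
piecewiseLinearMap <- function(values, knotsX, knotsY) {
  stats::approx(knotsX, knotsY, xout = values, rule = 2)$y
}

trapzQuad <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Evaluate an expression with a temporary RNG seed, restoring global RNG
# state. The seed argument is forced first: it may itself be drawn from the
# caller's RNG stream, which must advance before the state is saved.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Apply a rigid (or similarity) transform to a sulcal mesh
#'
#' Rotates, translates and optionally scales a mesh together with its
#' companion surfaces. Used to verify that all shape measures are invariant
#' under rigid motion and follow the expected scaling laws.
#'
#' @param mesh a \linkS4class{SulcalMesh}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric(3) (mm).
#' @param scale positive scalar.
#' @return The transformed \linkS4class{SulcalMesh}.
#' @export
transformSulcalMesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                                scale = 1) {
  tf <- function(V) sweep(scale * (V %*% t(rotation)), 2, translation, "+")
  mesh@vertices <- tf(mesh@vertices)
  mesh@companions <- lapply(mesh@companions, function(cc) {
    cc$vertices <- tf(cc$vertices); cc
  })
  mesh
}
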