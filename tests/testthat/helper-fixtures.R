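# Shared fixtures and independent oracles, all built in code.

# Analytic flat-sheet spec: 100 mm x 12 mm ribbon, 2.4 mm span, 3 mm thick.
flatSheetSpec <- function(resolution = 1) {
  sulcusSpec(length = 100,
             depthFn = function(y) rep(12, length(y)),
             profileFn = function(y) rep(0, length(y)),
             span = 2.4,
             thicknessFn = function(y) rep(3, length(y)),
             meshResolution = resolution, noiseSd = 0)
}

# Minimal valid mesh: a unit square of two triangles. Left edge is the
# superior end wall, right edge the inferior one; top/bottom rows are the
# ridges.
squareMesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  F <- rbind(c(1L, 2L, 3L), c(2L, 4L, 3L))
  SulcalMesh(V, F, topRidge = c(1L, 2L), bottomRidge = c(3L, 4L),
             endpointSuperior = 1L, endpointInferior = 2L)
}

randomRotation <- function(seed = 1) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Independent OLS oracle: explicit normal equations, no qr/lm machinery.
olsOracle <- function(y, X) {
  XtX <- t(X) %*% X
  XtXi <- solve(XtX)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(XtXi))
  t <- beta / se
  list(beta = beta[2], se = se[2], t = t[2],
       p = 2 * stats::pt(-abs(t[2]), df), df = df)
}

# Independent BH oracle: literal step-up definition.
bhOracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  qo <- pmin(rev(cummin(rev(m * po / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- qo
  # step-up rejection set: largest k with p_(k) <= k * alpha / m
  k <- which(po <= seq_len(m) * alpha / m)
  rejected <- rep(FALSE, m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  list(q = q, significant = rejected)
}

# Dense direct Laplace solve (independent oracle for the sparse path).
denseHarmonicOracle <- function(mesh, boundaryValues) {
  L <- as.matrix(sulcushape:::cotanLaplacian(mesh@vertices, mesh@triangles))
  bIdx <- as.integer(names(boundaryValues))
  iIdx <- setdiff(seq_len(nrow(L)), bIdx)
  field <- numeric(nrow(L))
  field[bIdx] <- boundaryValues
  field[iIdx] <- solve(L[iIdx, iIdx], -L[iIdx, bIdx, drop = FALSE] %*%
                         boundaryValues)
  field
}

# Hand-built 8-row cohort table for regression fixtures.
handCohort <- function() {
  data.frame(
    subject_id = paste0("H", 1:8),
    group = rep(c("case", "control"), 4),
    age_months = c(120, 131, 142, 118, 150, 127, 135, 140),
    gender = c(1, 0, 1, 1, 0, 1, 0, 0),
    inattention = c(60, 45, 66, 58, 44, 70, 50, 47),
    hyperactivity_impulsivity = c(72, 49, 75, 61, 52, 80, 48, 51),
    dsm_total = c(68, 47, 71, 62, 50, 74, 49, 52),
    stringsAsFactors = FALSE)
}

makeProfileCurve <- function(values) {
  new("ProfileCurve", positions = seq_along(values), values = as.numeric(values),
      nodeDistances = numeric(0), counts = integer(length(values)),
      interpolated = rep(FALSE, length(values)))
}
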