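# Covariate-adjusted group statistics: multiple linear regression with age
# and gender as covariates, applied to global metrics, position-wise curves
# and node-wise fields, with Benjamini-Hochberg FDR control and masked
# clinical-score correlations.

buildDesign <- function(cohort, predictor = c("group", "score"), score = NULL,
                        caseLevel = "case") {
  predictor <- match.arg(predictor)
  cohort <- validateCohortTable(cohort)
  if (predictor == "group") {
    if (!caseLevel %in% cohort$group)
      stop("caseLevel '", caseLevel, "' not found among group labels")
    pred <- as.numeric(cohort$group == caseLevel)
  } else {
    if (is.null(score) || !score %in% names(cohort))
      stop("predictor = 'score' needs a valid score column name")
    pred <- cohort[[score]]
  }
  X <- cbind(intercept = 1, predictor = pred, age = cohort$age_months,
             gender = cohort$gender)
  if (nrow(X) < 5L)
    stop("need at least 5 subjects (df = n - 4 >= 1)")
  if (qr(X)$rank < ncol(X)) stop("collinear design matrix")
  X
}

# Least-squares fit of Y (n x K) on X (n x 4); returns the statistics of the
# predictor coefficient (column 2) for every response column.
olsMatrix <- function(Y, X) {
  n <- nrow(X); pcol <- ncol(X)
  df <- n - pcol
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  fitted <- X %*% coefs
  res <- Y - fitted
  rss <- colSums(res^2)
  varY <- colSums(sweep(Y, 2, colMeans(Y))^2)
  degenerate <- rss <= 1e-12 * pmax(varY, 1e-12) | varY <= 1e-24
  sigma2 <- rss / df
  XtXi22 <- chol2inv(chol(crossprod(X)))[2, 2]
  se <- sqrt(sigma2 * XtXi22)
  beta <- coefs[2, ]
  t <- beta / se
  p <- 2 * pt(-abs(t), df)
  t[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  list(beta = as.numeric(beta), se = as.numeric(se), t = as.numeric(t),
       p = as.numeric(p), df = df, degenerate = degenerate)
}

#' Covariate-adjusted linear model for one response
#'
#' Ordinary least squares of the response on [intercept, predictor, age,
#' gender]; the predictor is either the binary group indicator or a clinical
#' score. Reports the predictor coefficient, its t statistic (beta / SE) and
#' the two-sided p value from the Student t distribution with n - 4 degrees
#' of freedom.
#'
#' @param response numeric vector, one value per cohort row.
#' @param cohort a valid cohort table.
#' @param predictor "group" or "score".
#' @param score score column name when \code{predictor = "score"}.
#' @param caseLevel the group label coded 1 in the design.
#' @return list with \code{beta}, \code{se}, \code{t}, \code{p}, \code{df}
#'   and \code{degenerate} (TRUE when the residual variance vanishes).
#' @export
fitAdjustedModel <- function(response, cohort, predictor = c("group", "score"),
                             score = NULL, caseLevel = "case") {
  X <- buildDesign(cohort, predictor, score, caseLevel)
  if (length(response) != nrow(X))
    stop("response length does not match the cohort")
  if (anyNA(response)) stop("response contains missing values")
  r <- olsMatrix(matrix(response, ncol = 1), X)
  list(beta = r$beta, se = r$se, t = r$t, p = r$p, df = r$df,
       degenerate = r$degenerate[1])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values q_(i) = min over j >= i of m p_(j) / j, capped at
#' 1; a unit is significant when q <= alpha.
#'
#' @param p p values in [0, 1] (NAs allowed; excluded from the family).
#' @param alpha FDR level.
#' @return list with \code{q} and logical \code{significant}.
#' @export
bhFdr <- function(p, alpha = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  sig <- !is.na(q) & q <= alpha
  list(q = q, significant = sig)
}

contiguousRuns <- function(idx) {
  if (!length(idx)) return(data.frame(start = integer(0), end = integer(0)))
  br <- c(0, which(diff(idx) != 1), length(idx))
  data.frame(start = idx[br[-length(br)] + 1], end = idx[br[-1]])
}

makeStatMap <- function(unit, ids, fit, alpha, extra = list()) {
  fdr <- bhFdr(fit$p, alpha)
  if (any(fit$degenerate))
    warning(sum(fit$degenerate), " degenerate unit(s) excluded from FDR")
  if (identical(unit, "position")) {
    runs <- contiguousRuns(which(fdr$significant))
    extra$intervals <- runs
  }
  new("StatMap", unit = unit, ids = as.character(ids), beta = fit$beta,
      t = fit$t, p = fit$p, q = fdr$q, significant = fdr$significant,
      alpha = alpha, df = fit$df, extra = extra)
}

checkAligned <- function(mat, cohort) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) != nrow(cohort))
    stop("matrix rows must match cohort rows")
  rn <- rownames(mat)
  if (!is.null(rn) && !identical(rn, as.character(cohort$subject_id)))
    stop("matrix row names do not match cohort subject order")
  tabg <- table(cohort$group)
  if (any(tabg < 2L)) stop("need at least 2 subjects per group")
  mat
}

#' Position-wise group analysis of curves
#'
#' Fits the covariate-adjusted group model at each y position of a
#' subjects-by-positions curve matrix (depth-position profiles or sulcal
#' profiles resampled to a common parameterization), applies BH-FDR across
#' the P positions, and reports contiguous significant runs as y intervals.
#'
#' @param curves numeric matrix, subjects x P, rows in cohort order.
#' @param cohort a valid cohort table.
#' @param alpha FDR level.
#' @param caseLevel group label coded 1.
#' @return A \linkS4class{StatMap} with unit "position"; significant y
#'   intervals in \code{extra$intervals}.
#' @export
positionwiseGroupAnalysis <- function(curves, cohort, alpha = 0.05,
                                      caseLevel = "case") {
  curves <- checkAligned(curves, cohort)
  X <- buildDesign(cohort, "group", caseLevel = caseLevel)
  fit <- olsMatrix(curves, X)
  makeStatMap("position", seq_len(ncol(curves)), fit, alpha)
}

#' Node-wise group analysis of template fields
#'
#' Fits the covariate-adjusted group model at every template node of a
#' subjects-by-nodes field matrix (template-resampled signed distances),
#' with BH-FDR across nodes. The default transform takes the absolute value
#' of the field (distance from the inertial plane regardless of side); the
#' signed option tests the raw field.
#'
#' @param fields numeric matrix, subjects x nodes, rows in cohort order.
#' @param cohort a valid cohort table.
#' @param alpha FDR level.
#' @param transform "abs" (default) or "signed".
#' @param caseLevel group label coded 1.
#' @return A \linkS4class{StatMap} with unit "node".
#' @export
nodewiseGroupAnalysis <- function(fields, cohort, alpha = 0.05,
                                  transform = c("abs", "signed"),
                                  caseLevel = "case") {
  transform <- match.arg(transform)
  fields <- checkAligned(fields, cohort)
  if (transform == "abs") fields <- abs(fields)
  X <- buildDesign(cohort, "group", caseLevel = caseLevel)
  fit <- olsMatrix(fields, X)
  makeStatMap("node", seq_len(ncol(fields)), fit, alpha,
              extra = list(transform = transform))
}

#' Masked clinical-score correlation
#'
#' Within a mask of template nodes (typically the nodes showing a
#' significant group difference), tests the association between the
#' per-node field and a clinical score across all subjects, adjusted for
#' age and gender: the score coefficient of the adjusted regression,
#' equivalent to a partial correlation. BH-FDR is applied within the mask.
#'
#' @param fields numeric matrix, subjects x nodes, rows in cohort order.
#' @param cohort a valid cohort table.
#' @param score score column name.
#' @param mask logical vector over nodes, or integer node indices; must be
#'   non-empty.
#' @param alpha FDR level.
#' @return A \linkS4class{StatMap} with unit "node"; ids are the masked
#'   node indices.
#' @export
maskedScoreCorrelation <- function(fields, cohort, score, mask, alpha = 0.05) {
  fields <- checkAligned(fields, cohort)
  if (is.logical(mask)) {
    if (length(mask) != ncol(fields)) stop("logical mask length must match nodes")
    mask <- which(mask)
  }
  mask <- as.integer(mask)
  if (!length(mask)) stop("mask is empty: no nodes to correlate")
  if (any(mask < 1L | mask > ncol(fields))) stop("mask indices out of range")
  X <- buildDesign(cohort, "score", score = score)
  fit <- olsMatrix(fields[, mask, drop = FALSE], X)
  makeStatMap("node", mask, fit, alpha, extra = list(score = score))
}

#' Table-style report of the global measures
#'
#' Per metric (and hemisphere when present): group means and SDs plus the
#' covariate-adjusted group t and p.
#'
#' @param metrics data.frame with columns \code{subject_id}, optionally
#'   \code{hemi}, and one column per global measure, one row per
#'   subject/hemisphere, in cohort order within each hemisphere.
#' @param cohort a valid cohort table.
#' @param caseLevel group label treated as the case group.
#' @return data.frame with columns \code{metric}, \code{hemi},
#'   \code{mean_case}, \code{sd_case}, \code{mean_control},
#'   \code{sd_control}, \code{t}, \code{p}.
#' @export
globalReport <- function(metrics, cohort, caseLevel = "case") {
  cohort <- validateCohortTable(cohort)
  if (is.null(metrics$hemi)) metrics$hemi <- "L"
  metricCols <- setdiff(names(metrics), c("subject_id", "hemi"))
  rows <- list()
  for (h in unique(metrics$hemi)) {
    sub <- metrics[metrics$hemi == h, ]
    ord <- match(cohort$subject_id, sub$subject_id)
    if (anyNA(ord)) stop("metrics are missing subjects present in the cohort")
    sub <- sub[ord, ]
    isCase <- cohort$group == caseLevel
    for (m in metricCols) {
      v <- sub[[m]]
      fit <- fitAdjustedModel(v, cohort, "group", caseLevel = caseLevel)
      rows[[length(rows) + 1L]] <- data.frame(metric = m, hemi = h,
        mean_case = mean(v[isCase]), sd_case = sd(v[isCase]),
        mean_control = mean(v[!isCase]), sd_control = sd(v[!isCase]),
        t = fit$t, p = fit$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Significant y intervals of a position StatMap
#'
#' @param statMap a \linkS4class{StatMap} with unit "position".
#' @return data.frame with columns \code{start} and \code{end} (positions).
#' @export
significantIntervals <- function(statMap) {
  if (statMap@unit != "position") stop("intervals are defined for position maps")
  statMap@extra$intervals
}
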