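# Adjusted regression, BH-FDR, position/node-wise analyses and correlations.

test_that("the adjusted model matches the normal-equations oracle", {
  tab <- handCohort()
  X <- cbind(1, as.numeric(tab$group == "case"), tab$age_months, tab$gender)
  set.seed(2)
  for (rep in 1:5) {
    y <- rnorm(8, mean = 10 + 0.6 * X[, 2])
    fit <- fitAdjustedModel(y, tab)
    oracle <- olsOracle(y, X)
    expect_lt(abs(fit$beta - oracle$beta), 1e-8)
    expect_lt(abs(fit$t - oracle$t), 1e-8)
    expect_lt(abs(fit$p - oracle$p), 1e-8)
    expect_equal(fit$df, oracle$df)
  }
})

test_that("null p values are uniform", {
  tab <- simulateProfileCurves(nPerGroup = 21, seed = 13)$cohort
  X <- sulcushape:::buildDesign(tab, "group")
  set.seed(3)
  Y <- matrix(rnorm(42 * 1000), 42, 1000)
  p <- sulcushape:::olsMatrix(Y, X)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("covariates absorb covariate-driven responses", {
  tab <- handCohort()
  set.seed(9)
  y <- 2 * tab$age_months + rnorm(8, sd = 0.5)
  fit <- fitAdjustedModel(y, tab)
  expect_lt(abs(fit$beta), 1)       # mm-scale residual effect only
  expect_gt(fit$p, 0.1)
  # a perfectly fit response is flagged degenerate
  fitd <- fitAdjustedModel(2 * tab$age_months, tab)
  expect_true(fitd$degenerate)
  expect_true(is.na(fitd$p))
})

test_that("model preconditions are enforced", {
  tab <- handCohort()
  expect_error(fitAdjustedModel(1:4, tab[1:4, ]), "at least 5")
  tab2 <- tab
  tab2$gender <- 1
  expect_error(fitAdjustedModel(rnorm(8), tab2), "collinear")
  expect_error(fitAdjustedModel(c(rnorm(7), NA), tab), "missing")
})

test_that("bhFdr reproduces the hand-computed examples", {
  r1 <- bhFdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r1$significant))
  r2 <- bhFdr(c(0.04, 0.5, 0.9), alpha = 0.05)
  expect_false(any(r2$significant))
  r3 <- bhFdr(rep(1, 5))
  expect_equal(r3$q, rep(1, 5))
  expect_false(any(r3$significant))
  expect_error(bhFdr(c(0.2, 1.4)), "0, 1")
})

test_that("bhFdr equals the exhaustive step-up oracle on random vectors", {
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample.int(12, 1))^sample(c(0.5, 1, 3), 1)
    got <- bhFdr(p)
    want <- bhOracle(p)
    expect_lt(max(abs(got$q - want$q)), 1e-12)
    expect_identical(got$significant, want$significant)
  }
})

test_that("adding a constant case shift increases the group |t|", {
  tab <- simulateProfileCurves(nPerGroup = 10, seed = 44)$cohort
  set.seed(99)
  y <- rnorm(20)
  isCase <- tab$group == "case"
  s <- sign(fitAdjustedModel(y, tab)$beta)  # shift along the existing effect
  tvals <- vapply(s * c(0, 0.5, 1, 2), function(delta) {
    abs(fitAdjustedModel(y + delta * isCase, tab)$t)
  }, numeric(1))
  expect_true(all(diff(tvals) > 0))
})

test_that("position-wise analysis recovers an injected window", {
  s <- simulateProfileCurves(effectWindow = c(50, 60), amplitude = 1.8,
                             seed = 10)
  sm <- positionwiseGroupAnalysis(s$curves, s$cohort)
  expect_s4_class(sm, "StatMap")
  expect_gt(mean(sm@significant[50:60]), 0.7)
  expect_lt(mean(sm@significant[-(45:65)]), 0.2)
  iv <- significantIntervals(sm)
  expect_true(any(iv$start <= 55 & iv$end >= 55))
})

test_that("subject permutation leaves the analysis invariant", {
  s <- simulateProfileCurves(effectWindow = c(40, 50), amplitude = 1,
                             seed = 12)
  sm1 <- positionwiseGroupAnalysis(s$curves, s$cohort)
  set.seed(1)
  perm <- sample(nrow(s$curves))
  sm2 <- positionwiseGroupAnalysis(s$curves[perm, ], s$cohort[perm, ])
  expect_equal(sm2@p, sm1@p, tolerance = 1e-12)
  expect_identical(sm2@significant, sm1@significant)
})

test_that("analyses refuse degenerate cohorts and misaligned rows", {
  s <- simulateProfileCurves(nPerGroup = 2, seed = 3)
  one <- c(1, 3)  # one subject per group
  expect_error(positionwiseGroupAnalysis(s$curves[one, ], s$cohort[one, ]),
               "at least 2")
  bad <- s$curves
  rownames(bad) <- rev(rownames(bad))
  expect_error(positionwiseGroupAnalysis(bad, s$cohort), "row names")
})

test_that("node-wise analysis recovers a planted patch (Jaccard >= 0.5)", {
  nNodes <- 400L
  patch <- 150:199
  set.seed(70)
  tab <- simulateProfileCurves(nPerGroup = 21, seed = 7)$cohort
  fields <- matrix(rnorm(42 * nNodes, sd = 1.0), 42, nNodes)
  rownames(fields) <- tab$subject_id
  isCase <- tab$group == "case"
  fields[isCase, patch] <- fields[isCase, patch] + 1.5
  sm <- nodewiseGroupAnalysis(fields, tab, transform = "signed")
  sig <- which(sm@significant)
  jac <- length(intersect(sig, patch)) / length(union(sig, patch))
  expect_gte(jac, 0.5)
})

test_that("node-wise nulls rarely reject and constants are flagged", {
  set.seed(30)
  clean <- replicate(30, {
    tab <- simulateProfileCurves(nPerGroup = 21, seed = sample.int(1e6, 1))$cohort
    fields <- matrix(rnorm(42 * 300), 42, 300)
    rownames(fields) <- tab$subject_id
    sum(nodewiseGroupAnalysis(fields, tab)@significant) == 0
  })
  expect_gte(mean(clean), 0.9)
  tab <- simulateProfileCurves(nPerGroup = 5, seed = 2)$cohort
  fields <- matrix(rnorm(10 * 20), 10, 20)
  fields[, 7] <- 4  # constant across subjects
  rownames(fields) <- tab$subject_id
  expect_warning(sm <- nodewiseGroupAnalysis(fields, tab, transform = "signed"),
                 "degenerate")
  expect_true(is.na(sm@q[7]))
  expect_false(sm@significant[7])
})

test_that("masked score correlation finds planted couplings", {
  set.seed(150)
  tab <- simulateProfileCurves(nPerGroup = 21, seed = 15)$cohort
  nNodes <- 120L
  fields <- matrix(rnorm(42 * nNodes), 42, nNodes)
  planted <- 10:19
  # planted nodes share a latent shape factor z; the score is coupled to z
  # so that each planted node has expected r ~ 0.6 with the score
  z <- rnorm(42)
  fields[, planted] <- sqrt(0.7) * z + sqrt(0.3) * fields[, planted]
  rownames(fields) <- tab$subject_id
  tab$hyperactivity_impulsivity <- 50 +
    12 * (0.7 * z + sqrt(1 - 0.7^2) * rnorm(42))
  mask <- c(planted, 60:79)
  sm <- maskedScoreCorrelation(fields, tab, "hyperactivity_impulsivity", mask)
  expect_identical(sm@ids, as.character(mask))
  expect_gt(mean(sm@p[seq_along(planted)] < 0.05), 0.5)
  expect_true(all(sm@beta[seq_along(planted)][sm@p[seq_along(planted)] < 0.05] > 0))
  expect_error(maskedScoreCorrelation(fields, tab, "inattention", integer(0)),
               "empty")
})

test_that("independent scores show ~alpha-level within-mask rates", {
  set.seed(16)
  rates <- replicate(40, {
    tab <- simulateProfileCurves(nPerGroup = 21, seed = sample.int(1e6, 1))$cohort
    fields <- matrix(rnorm(42 * 50), 42, 50)
    rownames(fields) <- tab$subject_id
    sm <- maskedScoreCorrelation(fields, tab, "inattention", 1:50)
    mean(sm@p < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("the global report has the Table-style schema", {
  tab <- handCohort()
  metrics <- data.frame(subject_id = tab$subject_id, hemi = "L",
                        average_depth = rnorm(8, 13),
                        surface_area = rnorm(8, 3500, 100))
  rep <- globalReport(metrics, tab)
  expect_identical(names(rep), c("metric", "hemi", "mean_case", "sd_case",
                                 "mean_control", "sd_control", "t", "p"))
  expect_equal(nrow(rep), 2L)
  isCase <- tab$group == "case"
  expect_equal(rep$mean_case[rep$metric == "average_depth"],
               mean(metrics$average_depth[isCase]))
})
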