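# End-to-end orchestration: simulate -> parameterize -> landmark
# reparameterization -> template correspondence -> metrics -> group
# statistics -> masked correlations, with deterministic seeding and a
# written manifest, plus a report generator working from saved outputs only.

pipelineDefaults <- function() {
  list(seed = 1L, nPerGroup = 21L, P = 100L, alpha = 0.05,
       depthMode = "geodesic", hemisphere = "L",
       landmarkTarget = "group",   # "group" (per-group averages) or "pooled"
       templateSeed = 20L, meshResolution = c(0.8, 1.5),
       nullCohort = FALSE, spanMaxNodes = 150L,
       thicknessMethod = "field", outputDir = NULL)
}

validateRunConfig <- function(config) {
  def <- pipelineDefaults()
  unknown <- setdiff(names(config), c(names(def), "cohortSpec"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, config)
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)")
  if (cfg$P < 10L) stop("P must be at least 10")
  if (cfg$nPerGroup < 2L) stop("nPerGroup must be at least 2")
  if (!cfg$landmarkTarget %in% c("group", "pooled"))
    stop("landmarkTarget must be 'group' or 'pooled'")
  if (is.null(cfg$outputDir)) stop("config needs an outputDir")
  cfg
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full sulcal morphometry pipeline
#'
#' Executes, in order: cohort simulation, harmonic parameterization,
#' landmark detection and piecewise-linear reparameterization (per-group or
#' pooled targets), template resampling of the signed-distance field,
#' depth-position and sulcal-profile curves, the Table-style global report,
#' position-wise and node-wise covariate-adjusted group analyses with
#' BH-FDR, and masked clinical-score correlations. All outputs plus a JSON
#' run manifest are written to \code{outputDir}; re-running with the same
#' config reproduces every table exactly.
#'
#' @param config a named list (or path to a YAML file) with keys
#'   \code{seed}, \code{nPerGroup}, \code{P}, \code{alpha},
#'   \code{depthMode}, \code{hemisphere}, \code{landmarkTarget},
#'   \code{templateSeed}, \code{meshResolution}, \code{nullCohort},
#'   \code{spanMaxNodes}, \code{thicknessMethod}, \code{outputDir};
#'   alternatively \code{cohortSpec} may hold a ready
#'   \linkS4class{CohortSpec}.
#' @return Invisibly, a list with every intermediate and final object.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateRunConfig(config)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)

  spec <- config$cohortSpec
  if (is.null(spec)) {
    base <- sulcusSpec(meshResolution = cfg$meshResolution, noiseSd = 0.05)
    spec <- if (cfg$nullCohort) {
      cs <- cohortSpec(nPerGroup = cfg$nPerGroup, base = base,
                       groupEffects = list(), seed = cfg$seed)
      cs@scoreModel$coupling <- NULL
      cs
    } else {
      cohortSpec(nPerGroup = cfg$nPerGroup, base = base, seed = cfg$seed)
    }
  }

  cohort <- stageTry("simulate", generateCohort(spec, hemisphere = cfg$hemisphere))
  tab <- cohortTable(cohort)
  n <- nrow(tab)

  template <- stageTry("template",
    buildTemplate(sulcusSpec(meshResolution = cfg$meshResolution,
                             seed = cfg$templateSeed), P = cfg$P))

  paramList <- vector("list", n)
  lmList <- vector("list", n)
  stageTry("parameterize", for (i in seq_len(n)) {
    ps <- parameterize(meshes(cohort)[[i]])
    prof <- profileCurve(ps, P = cfg$P)
    lm <- detectLandmarks(prof)
    if (lm$defined) { ps@L1 <- lm$L1; ps@L2 <- lm$L2 }
    paramList[[i]] <- ps
    lmList[[i]] <- lm
  })

  stageTry("reparameterize", {
    defined <- vapply(lmList, `[[`, logical(1), "defined")
    if (any(defined)) {
      groupsOf <- tab$group
      for (g in unique(groupsOf)) {
        sel <- if (cfg$landmarkTarget == "group") which(groupsOf == g & defined)
               else which(defined)
        if (!length(sel)) next
        tgt <- groupTargetLandmarks(lmList[sel])
        for (i in which(groupsOf == g & defined))
          paramList[[i]] <- reparameterize(paramList[[i]], tgt$L1, tgt$L2)
      }
    }
  })

  dppCurves <- matrix(NA_real_, n, cfg$P)
  profCurves <- matrix(NA_real_, n, cfg$P)
  dFields <- matrix(NA_real_, n, nrow(vertices(template)))
  rownames(dppCurves) <- rownames(profCurves) <- rownames(dFields) <- tab$subject_id
  stageTry("curves", for (i in seq_len(n)) {
    ps <- paramList[[i]]
    dppCurves[i, ] <- depthValues(depthPositionProfile(ps, P = cfg$P,
                                                       mode = cfg$depthMode))
    pc <- profileCurve(ps, P = cfg$P)
    profCurves[i, ] <- profileValues(pc)
    dFields[i, ] <- resampleToTemplate(ps, template,
                                       list(d = pc@nodeDistances))$d
  })

  metricsDf <- stageTry("metrics", {
    rows <- lapply(seq_len(n), function(i) {
      gm <- as.data.frame(globalMetrics(paramList[[i]], P = cfg$P,
        depthMode = cfg$depthMode, spanMaxNodes = cfg$spanMaxNodes,
        thicknessMethod = cfg$thicknessMethod))
      cbind(data.frame(subject_id = tab$subject_id[i],
                       hemi = cfg$hemisphere), gm)
    })
    do.call(rbind, rows)
  })
  report <- stageTry("global-report", globalReport(metricsDf, tab))

  dppStats <- stageTry("group-analysis",
    positionwiseGroupAnalysis(dppCurves, tab, alpha = cfg$alpha))
  profStats <- stageTry("group-analysis",
    positionwiseGroupAnalysis(profCurves, tab, alpha = cfg$alpha))
  nodeStats <- stageTry("group-analysis",
    nodewiseGroupAnalysis(dFields, tab, alpha = cfg$alpha))

  correlations <- list()
  mask <- which(nodeStats@significant)
  if (length(mask)) {
    for (sc in c("hyperactivity_impulsivity", "inattention"))
      correlations[[sc]] <- stageTry("correlate",
        maskedScoreCorrelation(dFields, tab, sc, mask, alpha = cfg$alpha))
  }

  stageTry("write-outputs", {
    od <- cfg$outputDir
    write.csv(tab, file.path(od, "cohort.csv"), row.names = FALSE)
    write.csv(metricsDf, file.path(od, "global_metrics.csv"), row.names = FALSE)
    write.csv(report, file.path(od, "global_report.csv"), row.names = FALSE)
    writeCurves <- function(m, f) {
      df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
      names(df) <- c("subject_id", paste0("p", seq_len(ncol(m))))
      write.csv(df, file.path(od, f), row.names = FALSE)
    }
    writeCurves(dppCurves, "dpp_curves.csv")
    writeCurves(profCurves, "profile_curves.csv")
    write.csv(as.data.frame(dppStats), file.path(od, "positionwise_depth.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(profStats), file.path(od, "positionwise_profile.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(nodeStats), file.path(od, "nodewise_profile.csv"),
              row.names = FALSE)
    for (sc in names(correlations))
      write.csv(as.data.frame(correlations[[sc]]),
                file.path(od, paste0("correlation_", sc, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(list(
      landmarks = lapply(lmList, function(l) l[c("L1", "L2", "defined")]),
      intervals = list(depth = significantIntervals(dppStats),
                       profile = significantIntervals(profStats))),
      file.path(od, "landmarks.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    manifest <- list(
      package = "sulcushape",
      version = as.character(utils::packageVersion("sulcushape")),
      config = cfg[setdiff(names(cfg), "outputDir")],
      nSubjects = n, templateNodes = ncol(dFields),
      maskSize = length(mask))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(config = cfg, cohort = cohort, template = template,
    parameterized = paramList, landmarks = lmList, dppCurves = dppCurves,
    profileCurves = profCurves, dFields = dFields, metrics = metricsDf,
    report = report, dppStats = dppStats, profileStats = profStats,
    nodeStats = nodeStats, correlations = correlations))
}

#' Summarize a completed pipeline run
#'
#' Builds a human-readable summary purely from the files a
#' \code{\link{runPipeline}} call wrote (no recomputation): cohort
#' composition, global-measure table, significant y intervals of the depth
#' and profile analyses, node-wise counts and the correlation summaries.
#'
#' @param outputDir the pipeline output directory.
#' @return Character vector of report lines (also printed).
#' @export
makeReport <- function(outputDir) {
  need <- c("manifest.json", "cohort.csv", "global_report.csv",
            "positionwise_depth.csv", "positionwise_profile.csv",
            "nodewise_profile.csv", "landmarks.json")
  missing <- need[!file.exists(file.path(outputDir, need))]
  if (length(missing))
    stop("missing pipeline outputs: ", paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(outputDir, "manifest.json"),
                                  simplifyVector = TRUE)
  tab <- read.csv(file.path(outputDir, "cohort.csv"))
  rep <- read.csv(file.path(outputDir, "global_report.csv"))
  lmj <- jsonlite::read_json(file.path(outputDir, "landmarks.json"),
                             simplifyVector = TRUE)
  node <- read.csv(file.path(outputDir, "nodewise_profile.csv"))
  lines <- c(
    sprintf("sulcushape run (package %s)", manifest$version),
    sprintf("Cohort: %d subjects (%s)", nrow(tab),
            paste(sprintf("%s n=%d", names(table(tab$group)), table(tab$group)),
                  collapse = ", ")),
    "", "Global measures (mean +/- SD; covariate-adjusted t, p):")
  for (i in seq_len(nrow(rep)))
    lines <- c(lines, sprintf(
      "  %-18s %s  case %6.2f +/- %5.2f | control %6.2f +/- %5.2f  t=%6.2f p=%.4f",
      rep$metric[i], rep$hemi[i], rep$mean_case[i], rep$sd_case[i],
      rep$mean_control[i], rep$sd_control[i], rep$t[i], rep$p[i]))
  fmtIv <- function(iv) {
    if (is.null(iv) || length(iv) == 0 || NROW(iv) == 0) return("none")
    paste(sprintf("%d <= y <= %d", iv$start, iv$end), collapse = ", ")
  }
  lines <- c(lines, "",
    sprintf("Significant depth intervals:   %s", fmtIv(lmj$intervals$depth)),
    sprintf("Significant profile intervals: %s", fmtIv(lmj$intervals$profile)),
    sprintf("Node-wise significant nodes:   %d of %d",
            sum(node$significant), nrow(node)))
  for (sc in c("hyperactivity_impulsivity", "inattention")) {
    f <- file.path(outputDir, paste0("correlation_", sc, ".csv"))
    if (file.exists(f)) {
      cr <- read.csv(f)
      lines <- c(lines, sprintf(
        "Masked correlation with %s: %d/%d nodes significant (%d neg, %d pos)",
        sc, sum(cr$significant), nrow(cr),
        sum(cr$significant & cr$beta < 0), sum(cr$significant & cr$beta > 0)))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
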