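## End-to-end pipeline: QC -> cleaning -> connectivity -> degree -> group
## test -> behavior correlations -> within/between post-hoc -> CPM.

#' Pipeline configuration
#'
#' Defaults are the analysis parameters of the emulated study: mean-FD
#' exclusion at 0.25 mm, scrubbing at 0.5 mm, a 0.01-0.08 Hz passband, the
#' 2-10% density sweep, 5000 permutations for group and behavior inference,
#' family alpha 0.025 for the two behavioral outcomes, CPM selection threshold
#' 0.01 with 1000 permutations, and the pooled two-sample t test.
#'
#' @param sweep density sweep.
#' @param meanFDThreshold,scrubFDThreshold motion QC thresholds (mm).
#' @param bandLow,bandHigh passband (Hz).
#' @param filterOrder Butterworth order.
#' @param nPermGroup,nPermBehavior,nPermPrediction permutation counts.
#' @param groupAlpha FDR level for the group test.
#' @param familyAlpha familywise threshold for the behavior correlations.
#' @param pSelect CPM selection threshold.
#' @param exclusiveP nominal-significance bound on the *other* group for the
#'   post-hoc "exclusively significant" rule.
#' @param posthocAlpha significance level of the post-hoc within/between
#'   correlations.
#' @param tTestVariant `"pooled"` or `"welch"`.
#' @param seed integer seed for all stochastic stages.
#' @return named list of validated settings.
#' @export
pipelineConfig <- function(sweep = densitySweep(),
                           meanFDThreshold = 0.25, scrubFDThreshold = 0.5,
                           bandLow = 0.01, bandHigh = 0.08, filterOrder = 2L,
                           nPermGroup = 5000L, nPermBehavior = 5000L,
                           nPermPrediction = 1000L,
                           groupAlpha = 0.05, familyAlpha = 0.025,
                           pSelect = 0.01, exclusiveP = 0.05,
                           posthocAlpha = 0.05,
                           tTestVariant = c("pooled", "welch"), seed = 1L) {
  checkSweep(sweep)
  .assert(meanFDThreshold > 0 && scrubFDThreshold > 0, "QC thresholds must be positive")
  .assert(bandLow >= 0 && bandLow < bandHigh, "invalid passband")
  list(sweep = sweep, meanFDThreshold = meanFDThreshold,
       scrubFDThreshold = scrubFDThreshold, bandLow = bandLow,
       bandHigh = bandHigh, filterOrder = as.integer(filterOrder),
       nPermGroup = as.integer(nPermGroup),
       nPermBehavior = as.integer(nPermBehavior),
       nPermPrediction = as.integer(nPermPrediction),
       groupAlpha = groupAlpha, familyAlpha = familyAlpha,
       pSelect = pSelect, exclusiveP = exclusiveP,
       posthocAlpha = posthocAlpha,
       tTestVariant = match.arg(tTestVariant), seed = as.integer(seed))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Parcels significant exclusively in one group
#'
#' The post-hoc selection rule: significant (q below the family threshold) in
#' `inGroup`'s correlation result AND not even nominally significant
#' (p >= `exclusiveP`) in the other group's.
#'
#' @param resIn,resOther [AssociationResult-class]s for the two groups.
#' @param exclusiveP nominal bound for the other group (default 0.05).
#' @return integer parcel ids.
#' @export
exclusiveSignificant <- function(resIn, resOther, exclusiveP = 0.05) {
  tin <- resultTable(resIn); tot <- resultTable(resOther)
  sig <- tin$parcel_id[tin$significant]
  nominal <- tot$parcel_id[tot$p < exclusiveP]
  setdiff(sig, nominal)
}

#' Run the full degree-centrality pipeline on a cohort directory
#'
#' Consumes the layout written by [writeCohort()] (manifest, parcellation,
#' behavior, per-subject time series and motion) and executes: framewise
#' displacement QC (mean-FD exclusion, volume scrubbing), confound regression
#' (six motion parameters plus the global signal) and band-pass filtering,
#' Fisher-z connectivity, composite weighted degree with within/between
#' decomposition, group permutation testing, permutation-calibrated
#' correlations of degree with combined accuracy and reaction time (overall
#' and per group), the within/between post-hoc analysis on parcels significant
#' exclusively in patients, and degree-based CPM. All stage outputs, a run
#' log and a provenance record (config, seed, package version, input
#' checksums) are written under `outDir`.
#'
#' @param inputDir cohort directory (see [writeCohort()]).
#' @param outDir output directory.
#' @param config a [pipelineConfig()] list.
#' @return (invisibly) a list with the in-memory stage results: `qc`,
#'   `degrees` ([DegreeExperiment-class]), `groupTest`, `behaviorTests`,
#'   `posthoc`, `prediction`, `behaviorCompare`.
#' @export
runPipeline <- function(inputDir, outDir, config = pipelineConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)

  manifest <- .stage("read", {
    p <- file.path(inputDir, "manifest.json")
    .assert(file.exists(p), sprintf("no manifest.json in %s", inputDir))
    jsonlite::read_json(p, simplifyVector = FALSE)
  })
  parc <- .stage("read", readParcellation(file.path(inputDir, "parcellation.tsv")))
  behavior <- .stage("read", readBehavior(file.path(inputDir, "behavior.tsv")))
  tr <- manifest$tr %||% 3
  subjects <- manifest$subjects
  logLine("read: %d subjects, %d parcels, TR %g s", length(subjects),
          nParcels(parc), tr)

  ## --- motion QC ------------------------------------------------------------
  qc <- .stage("qc", {
    rows <- lapply(subjects, function(s) {
      motion <- readMotion(file.path(inputDir, s$motion))
      fd <- framewiseDisplacement(motion)
      q <- motionQC(fd, config$meanFDThreshold, config$scrubFDThreshold)
      data.frame(subject_id = s$subject_id, group = s$group,
                 mean_fd = q$meanFD, scrubbed_pct = 100 * q$scrubbedFraction,
                 include = q$include, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  .writeTSV(qc, file.path(outDir, "qc.tsv"))
  keepIds <- qc$subject_id[qc$include]
  logLine("qc: excluded %d/%d subjects (mean FD > %.2f mm); mean scrubbed %.2f%%",
          sum(!qc$include), nrow(qc), config$meanFDThreshold,
          mean(qc$scrubbed_pct))
  subjects <- Filter(function(s) s$subject_id %in% keepIds, subjects)
  .assert(length(subjects) >= 10L, "fewer than 10 subjects survive motion QC")

  ## --- cleaning + connectivity + degree -------------------------------------
  nP <- nParcels(parc)
  total <- within <- between <- matrix(NA_real_, nP, length(subjects))
  groups <- character(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    groups[i] <- s$group
    ts <- .stage("clean", readTimeSeries(file.path(inputDir, s$ts)))
    motion <- readMotion(file.path(inputDir, s$motion))
    fd <- framewiseDisplacement(motion)
    q <- motionQC(fd, config$meanFDThreshold, config$scrubFDThreshold)
    clean <- .stage("clean", {
      .assert(ncol(ts) == nP, sprintf("subject %s: %d parcels, expected %d",
                                      s$subject_id, ncol(ts), nP))
      cleanTimeSeries(ts, tr = tr, confounds = cbind(motion, global = rowMeans(ts)),
                      bandLow = config$bandLow, bandHigh = config$bandHigh,
                      order = config$filterOrder)
    })
    C <- .stage("connectivity", connectivityMatrix(clean, keepMask = q$keepMask))
    pd <- .stage("degree", partitionDegree(C, parc, sweep = config$sweep))
    total[, i] <- pd$total; within[, i] <- pd$within; between[, i] <- pd$between
  }
  ids <- vapply(subjects, `[[`, "", "subject_id")
  colnames(total) <- colnames(within) <- colnames(between) <- ids
  rownames(total) <- rownames(within) <- rownames(between) <-
    as.data.frame(parc)$parcel_label
  behavior <- behavior[match(ids, behavior$subject_id), , drop = FALSE]
  .assert(!anyNA(behavior$subject_id), "behavior table is missing QC-passing subjects")
  dge <- DegreeExperiment(total, parc, within = within, between = between,
                          colData = cbind(behavior,
                                          qc[match(ids, qc$subject_id),
                                             c("mean_fd", "scrubbed_pct")]),
                          sweep = config$sweep)
  degTab <- cbind(as.data.frame(parc)[, c("parcel_id", "network")],
                  k_total = rowMeans(total), k_within = rowMeans(within),
                  k_between = rowMeans(between))
  .writeTSV(degTab, file.path(outDir, "degree_mean.tsv"))
  .writeTSV(cbind(data.frame(parcel_id = seq_len(nP)), as.data.frame(total)),
            file.path(outDir, "degree_total.tsv"))
  logLine("degree: %d subjects x %d parcels over sweep [%s]",
          ncol(total), nP, paste(config$sweep, collapse = ", "))

  ## --- group differences -----------------------------------------------------
  groupTest <- .stage("groupdiff",
    groupPermutationTest(dge, labels = groups, nPerm = config$nPermGroup,
                         seed = childSeed(config$seed, 101L),
                         alpha = config$groupAlpha))
  .writeTSV(resultTable(groupTest), file.path(outDir, "group_test.tsv"))
  logLine("groupdiff: %d parcels FDR-significant at %.2f",
          sum(resultTable(groupTest)$significant), config$groupAlpha)

  ## --- degree-behavior correlations -----------------------------------------
  outcomes <- c(accuracy = "acc_combined", rt = "rt_combined")
  cohorts <- list(all = rep(TRUE, length(ids)),
                  control = groups == "control",
                  patient = groups == "patient")
  behaviorTests <- list()
  k <- 0L
  for (oc in names(outcomes)) {
    for (ch in names(cohorts)) {
      k <- k + 1L
      sel <- cohorts[[ch]]
      res <- .stage("behav-corr",
        correlationPermutationTest(t(assay(dge, "total")[, sel, drop = FALSE]),
                                   behavior[[outcomes[[oc]]]][sel],
                                   nPerm = config$nPermBehavior,
                                   seed = childSeed(config$seed, 200L + k),
                                   familyAlpha = config$familyAlpha))
      behaviorTests[[paste(oc, ch, sep = "_")]] <- res
      .writeTSV(resultTable(res),
                file.path(outDir, sprintf("corr_%s_%s.tsv", oc, ch)))
    }
  }

  ## --- post-hoc within/between on exclusively-patient parcels ---------------
  posthoc <- .stage("posthoc", {
    rows <- list()
    for (oc in names(outcomes)) {
      excl <- exclusiveSignificant(behaviorTests[[paste0(oc, "_patient")]],
                                   behaviorTests[[paste0(oc, "_control")]],
                                   config$exclusiveP)
      sel <- cohorts$patient
      y <- behavior[[outcomes[[oc]]]][sel]
      for (pid in excl) {
        for (variant in c("within", "between")) {
          kv <- assay(dge, variant)[pid, sel]
          ct <- stats::cor.test(kv, y)
          rows[[length(rows) + 1L]] <-
            data.frame(outcome = oc, parcel_id = pid,
                       network = rowData(dge)$network[pid], variant = variant,
                       r = unname(ct$estimate), p = ct$p.value,
                       significant = ct$p.value < config$posthocAlpha)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(outcome = character(0), parcel_id = integer(0),
                 network = character(0), variant = character(0),
                 r = numeric(0), p = numeric(0), significant = logical(0))
  })
  .writeTSV(posthoc, file.path(outDir, "posthoc_within_between.tsv"))
  logLine("posthoc: %d parcel x variant correlations", nrow(posthoc))

  ## --- prediction ------------------------------------------------------------
  prediction <- .stage("predict",
    cpmLOOCV(dge, behavior$acc_combined, pSelect = config$pSelect,
             nPerm = config$nPermPrediction,
             seed = childSeed(config$seed, 300L)))
  .writeTSV(resultTable(prediction), file.path(outDir, "prediction.tsv"))
  .writeTSV(data.frame(parcel_id = seq_len(nP),
                       network = rowData(dge)$network,
                       prevalence = prevalence(prediction)),
            file.path(outDir, "prevalence.tsv"))
  jsonlite::write_json(list(r = prediction@r, p = prediction@p,
                            p_select = config$pSelect,
                            n_perm = config$nPermPrediction,
                            seed = config$seed),
                       file.path(outDir, "prediction_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logLine("predict: r = %.3f, permutation p = %.4f", prediction@r, prediction@p)

  ## --- behavioral group comparison -------------------------------------------
  behaviorCompare <- .stage("behavior", rbind(
    groupCompare(behavior, "accuracy", variant = config$tTestVariant),
    groupCompare(behavior, "rt", variant = config$tTestVariant)))
  .writeTSV(behaviorCompare, file.path(outDir, "behavior_compare.tsv"))

  ## --- provenance ------------------------------------------------------------
  inputs <- c(file.path(inputDir, "manifest.json"),
              file.path(inputDir, "parcellation.tsv"),
              file.path(inputDir, "behavior.tsv"))
  provenance <- list(
    config = config,
    package = list(name = "HubDegree",
                   version = as.character(utils::packageVersion("HubDegree")),
                   r_version = paste(R.version$major, R.version$minor, sep = ".")),
    input_checksums = as.list(tools::md5sum(inputs)),
    n_subjects_input = nrow(qc), n_subjects_analyzed = length(ids))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(qc = qc, degrees = dge, groupTest = groupTest,
                 behaviorTests = behaviorTests, posthoc = posthoc,
                 prediction = prediction, behaviorCompare = behaviorCompare))
}
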