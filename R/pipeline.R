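# End-to-end experiment runners: generate a synthetic cohort, push it
# through the full analysis (indices, filters, statistics) and emit tidy
# tables, reproducibly from a single seed.

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the behavioral experiment end to end
#'
#' Generates a cohort with [genBehaviorCohort()], computes per-trial
#' avoidance indices over the 2-5 s window, applies the exclusion filters
#' (trial-level label filters, hyperactive flies, high-baseline flies),
#' summarizes behavior probabilities over the initial 5 s of recording and
#' their puff-induced changes, and tests the per-fly change in avoidance
#' index (and in walking probability) against zero with the normality-gated
#' harness.
#'
#' @param cfg a [syntheticConfig()].
#' @param arenaCfg an [arenaConfig()].
#' @param outDir optional directory; when given, tables are written as CSV
#'   plus a `run_info.json` with the seed and a config hash.
#' @return list with `trials`, `flyMeans`, `deltaAI`, `behaviorProbs`,
#'   `deltaProbs`, `exclusions`, `stats`, `runInfo`.
#' @export
runBehaviorExperiment <- function(cfg = syntheticConfig(),
                                  arenaCfg = arenaConfig(),
                                  outDir = NULL) {
  cohort <- genBehaviorCohort(cfg, arenaCfg)
  trials <- avoidanceTable(cohort)

  # trial-level label filters
  labKeys <- unique(cohort$labels[, c("fly_id", "trial")])
  excl <- lapply(seq_len(nrow(labKeys)), function(i) {
    st <- cohort$labels[cohort$labels$fly_id == labKeys$fly_id[i] &
                          cohort$labels$trial == labKeys$trial[i], ]
    res <- applyTrialExclusions(st)
    data.frame(fly_id = labKeys$fly_id[i], trial = labKeys$trial[i],
               decision = res$decision,
               reason = paste(res$reasons, collapse = "; "))
  })
  excl <- do.call(rbind, excl)
  locomotionOK <- excl$decision == "keep"
  trials <- merge(trials, excl[, c("fly_id", "trial", "decision")],
                  by = c("fly_id", "trial"))
  usable <- trials[trials$decision == "keep" & is.finite(trials$ai), ]

  # behavior probabilities over the initial 5 s of recording, per trial
  probs <- lapply(seq_len(nrow(labKeys)), function(i) {
    st <- cohort$labels[cohort$labels$fly_id == labKeys$fly_id[i] &
                          cohort$labels$trial == labKeys$trial[i], ]
    p <- behaviorProbabilities(st, window = c(0, 5))
    cbind(data.frame(fly_id = labKeys$fly_id[i], trial = labKeys$trial[i],
                     condition = st$condition[1]), as.data.frame(as.list(p)))
  })
  probs <- do.call(rbind, probs)

  # hyperactivity filter: mean walking probability over puff- trials
  baseWalk <- stats::aggregate(walking ~ fly_id,
                               probs[probs$condition == "puff-", ], mean)
  names(baseWalk)[2] <- "p_walk_baseline"
  hyper <- excludeHyperactiveFlies(baseWalk)
  keptFlies <- hyper$kept$fly_id

  # per-fly condition means and high-baseline rejection
  flyMeans <- stats::aggregate(ai ~ fly_id + condition, usable, mean)
  names(flyMeans)[3] <- "mean_ai"
  flyMeans <- flyMeans[flyMeans$fly_id %in% keptFlies, ]
  baseline <- flyMeans[flyMeans$condition == "puff-",
                       c("fly_id", "mean_ai")]
  names(baseline)[2] <- "baseline_ai"
  rej <- rejectHighBaseline(baseline)
  flyMeans <- flyMeans[flyMeans$fly_id %in% rej$kept$fly_id, ]

  # flies can lose a whole condition when every trial in it had zero
  # in-window displacement; change scores need both conditions
  both <- names(which(table(flyMeans$fly_id) == 2L))
  dAI <- deltaAvoidance(flyMeans[flyMeans$fly_id %in% both, ])
  dProbs <- deltaProbabilities(
    probs[probs$fly_id %in% intersect(keptFlies, rej$kept$fly_id), ])

  statRows <- rbind(
    runStatTest(list(dAI$delta_ai)),
    runStatTest(list(dProbs$walking)))
  statRows$comparison <- c("delta_avoidance_vs_0", "delta_walking_vs_0")
  statRows <- adjustResults(statRows)

  runInfo <- list(seed = cfg$seed, config_hash = configHash(cfg),
                  n_flies = cfg$nFlies,
                  n_excluded_hyperactive = hyper$n_excluded,
                  n_rejected_baseline = length(rej$rejected),
                  rejection_fraction = rej$rejection_fraction)
  out <- list(trials = trials, flyMeans = flyMeans, deltaAI = dAI,
              behaviorProbs = probs, deltaProbs = dProbs,
              exclusions = excl, stats = statRows, runInfo = runInfo)
  if (!is.null(outDir)) writeBehaviorRun(out, outDir)
  out
}

writeBehaviorRun <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("trials", "flyMeans", "deltaAI", "behaviorProbs",
               "deltaProbs", "exclusions", "stats"))
    write.csv(run[[nm]], file.path(outDir, paste0(nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(run$runInfo, file.path(outDir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' Run the imaging experiment end to end
#'
#' Generates calcium cohorts under the forward and reverse stimulus
#' schedules, pools the cells, computes dF/F0 and z-scores, classifies puff
#' responders on the first puff block, computes the responder-restricted
#' delta band power over the puff / pre-puff visual / post-puff visual
#' windows, peak responses, and the cross-cell mean spectrum.
#'
#' @param cfg a [syntheticConfig()].
#' @param nCells cells per schedule direction.
#' @param schedules directions to run (default both, pooled).
#' @param outDir optional output directory for CSV tables.
#' @return list with `responders` (per-cell flags and ground truth),
#'   `peaks`, `deltaPower` (pooled responder-restricted table),
#'   `perSchedule` (per-direction tables), `crossSpectrum`, `runInfo`.
#' @export
runImagingExperiment <- function(cfg = syntheticConfig(), nCells = 100L,
                                 schedules = c("forward", "reverse"),
                                 outDir = NULL) {
  perSched <- list()
  respRows <- list()
  peakRows <- list()
  pooled <- list()
  for (sc in schedules) {
    scCfg <- cfg
    scCfg$seed <- childSeed(cfg$seed, match(sc, c("forward", "reverse")))
    ce <- genCalciumCohort(scCfg, nCells, imagingSchedule(sc))
    ce <- zScoreTrace(deltaFOverF(ce))
    flags <- classifyResponder(ce)
    truth <- SummarizedExperiment::rowData(ce)$responder
    win <- defaultAnalysisWindows(ce)
    dff <- SummarizedExperiment::assay(ce, "dff")
    fs <- samplingRate(ce)
    pk <- vapply(seq_len(nrow(ce)), function(i)
      peakResponse(dff[i, ], win$puff, fs)$peak, numeric(1))
    bl <- vapply(seq_len(nrow(ce)), function(i)
      peakResponse(dff[i, ], win$puff, fs)$baseline, numeric(1))
    rrd <- responderRestrictedDelta(ce, responders = flags)
    perSched[[sc]] <- list(experiment = ce, deltaPower = rrd,
                           windows = win)
    respRows[[sc]] <- data.frame(schedule = sc, cell = rownames(ce),
                                 responder = flags, truth = truth)
    peakRows[[sc]] <- data.frame(schedule = sc, cell = rownames(ce),
                                 peak_dff = pk, baseline_dff = bl,
                                 responder = flags)
    pooled[[sc]] <- rrd$perCell
  }
  pooledPerCell <- do.call(rbind, pooled)
  pooledMean <- stats::aggregate(delta_power ~ band + window,
                                 pooledPerCell, mean)
  first <- perSched[[1]]$experiment
  Z <- SummarizedExperiment::assay(first, "z")
  nSpec <- min(nrow(first), 25L)
  specs <- lapply(seq_len(nSpec), function(i)
    morletCWT(Z[i, ], samplingRate(first)))
  crossSpec <- averageCrossSpectrum(specs)
  out <- list(responders = do.call(rbind, respRows),
              peaks = do.call(rbind, peakRows),
              deltaPower = list(mean = pooledMean, perCell = pooledPerCell),
              perSchedule = perSched,
              crossSpectrum = crossSpec,
              runInfo = list(seed = cfg$seed, config_hash = configHash(cfg),
                             n_cells = nCells, schedules = schedules))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$responders, file.path(outDir, "responders.csv"),
              row.names = FALSE)
    write.csv(out$peaks, file.path(outDir, "peaks.csv"), row.names = FALSE)
    write.csv(out$deltaPower$mean, file.path(outDir, "delta_power.csv"),
              row.names = FALSE)
    jsonlite::write_json(out$runInfo, file.path(outDir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
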