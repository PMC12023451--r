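## End-to-end orchestration: demo cohort generation, per-cell measurement,
## group comparisons, behavioural summaries, reproducibility manifest.

.demoPresets <- function() {
  list(
    WT = list(
      membrane = list(rin = 133, cm = 90, rs = 12, sag = 0.04,
                      noiseCc = 0.3, noiseVc = 2),
      spiking = list(rheobase = 210, gain = 0.09, threshold = -51,
                     peak = 49),
      events = list(rate = 3.8, meanlog = log(10), sdlog = 0.3),
      behavior = list(pPlus = c(0.55, 0.7, 0.85, 0.92, 0.95, 0.97, 0.97,
                                0.97, 0.97, 0.97),
                      pMinus = c(0.5, 0.4, 0.25, 0.15, 0.1, 0.05, 0.05,
                                 0.05, 0.05, 0.05))),
    KO = list(
      membrane = list(rin = 165, cm = 82, rs = 13, sag = 0.04,
                      noiseCc = 0.3, noiseVc = 2),
      spiking = list(rheobase = 115, gain = 0.135, threshold = -56.5,
                     peak = 42),
      events = list(rate = 3.8, meanlog = log(11), sdlog = 0.3),
      behavior = list(pPlus = c(0.55, 0.7, 0.85, 0.92, 0.95, 0.97, 0.97,
                                0.97, 0.97, 0.97),
                      pMinus = c(0.5, 0.4, 0.25, 0.15, 0.1, 0.05, 0.05,
                                 0.05, 0.05, 0.05))))
}

#' Generate a demo dataset of two synthetic cohorts
#'
#' Writes a fixture directory with two cohorts of cells (WT-like and KO-like
#' presets: the KO preset has a lower rheobase, steeper F-I gain and a more
#' hyperpolarised spike threshold) plus behavioural sessions, each with
#' ground truth. Per cell: an input-resistance protocol, a time-constant
#' protocol, a voltage-clamp Rs/Cm protocol, an F-I protocol, a fine rheobase
#' protocol, and a spontaneous-PSC recording.
#'
#' @param dir output directory.
#' @param seed integer seed; the dataset is fully reproducible.
#' @param nCellsPerGroup cells per cohort (12 matches the study's typical n).
#' @param nSessionsPerGroup behavioural sessions per cohort.
#' @param dt sampling interval for generated traces, s.
#' @param synapticDuration PSC recording length per cell, s.
#' @return the manifest list (cells, sessions), invisibly; files under `dir`.
#' @export
makeDemoDataset <- function(dir, seed = 1, nCellsPerGroup = 12,
                            nSessionsPerGroup = 7, dt = 1e-4,
                            synapticDuration = 20) {
  presets <- .demoPresets()
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sessions"), showWarnings = FALSE)
  set.seed(seed)
  cells <- list()
  for (grp in names(presets)) {
    pr <- presets[[grp]]
    for (i in seq_len(nCellsPerGroup)) {
      id <- sprintf("%s_cell%02d", grp, i)
      cellDir <- file.path(dir, "cells", id)
      jit <- function(x, cv = 0.1) x * rlnorm(1, 0, cv)
      mem <- membraneParams(restingPotential = -85,
                            inputResistance = jit(pr$membrane$rin),
                            capacitance = jit(pr$membrane$cm),
                            seriesResistance = jit(pr$membrane$rs, 0.05),
                            sagFraction = min(jit(pr$membrane$sag, 0.2), 0.5),
                            noiseSd = pr$membrane$noiseCc)
      spk <- spikingParams(rheobaseTrue = jit(pr$spiking$rheobase, 0.08),
                           gainTrue = jit(pr$spiking$gain, 0.08),
                           thresholdTrue = pr$spiking$threshold + rnorm(1, 0, 1),
                           apPeak = pr$spiking$peak + rnorm(1, 0, 2))
      memVc <- mem
      memVc@noiseSd <- pr$membrane$noiseVc

      writeSweepSet(genPassiveStepTraces(
        mem, stepProtocol(seq(-60, -20, 10), 0.1, 0.5), dt = dt,
        cellId = id, groupLabel = grp), file.path(cellDir, "rin"))
      writeSweepSet(genPassiveStepTraces(
        mem, stepProtocol(rep(-20, 10), 0.05, 0.1), dt = dt,
        cellId = id, groupLabel = grp), file.path(cellDir, "tau"))
      writeSweepSet(genPassiveStepTraces(
        memVc, stepProtocol(-(1:5), 0.02, 0.1), dt = dt, mode = "vc",
        cellId = id, groupLabel = grp), file.path(cellDir, "vc"))
      writeSweepSet(genPassiveStepTraces(
        mem, stepProtocol(seq(-120, -360, -30), 0.1, 0.5), dt = dt,
        cellId = id, groupLabel = grp), file.path(cellDir, "sag"))
      writeSweepSet(genSpikingTraces(
        spk, stepProtocol(seq(25, 675, 50), 0.1, 0.5), membrane = mem,
        dt = dt, noiseSd = 0.2, cellId = id, groupLabel = grp),
        file.path(cellDir, "fi"))
      rheoAmps <- seq(max(5, round(spk@rheobaseTrue / 5) * 5 - 30),
                      round(spk@rheobaseTrue / 5) * 5 + 30, 5)
      writeSweepSet(genSpikingTraces(
        spk, stepProtocol(rheoAmps, 0.1, 0.5), membrane = mem, dt = dt,
        cellId = id, groupLabel = grp), file.path(cellDir, "rheo"))
      spec <- eventGenSpec(rate = pr$events$rate,
                           amplitudeDist = list(name = "lognormal",
                                                meanlog = pr$events$meanlog,
                                                sdlog = pr$events$sdlog),
                           duration = synapticDuration)
      writeSweepSet(genSynapticTrace(spec, dt = dt, cellId = id,
                                     groupLabel = grp),
                    file.path(cellDir, "psc"))
      cells[[id]] <- list(id = id, group = grp,
                          truth = list(rin = mem@inputResistance,
                                       cm = mem@capacitance,
                                       rs = mem@seriesResistance,
                                       sag = mem@sagFraction,
                                       rheobase = spk@rheobaseTrue,
                                       gain = spk@gainTrue,
                                       threshold = spk@thresholdTrue))
    }
  }
  sessions <- character(0)
  for (grp in names(presets)) {
    pr <- presets[[grp]]
    for (a in seq_len(nSessionsPerGroup)) {
      id <- sprintf("%s_animal%02d", grp, a)
      ses <- genSession(sessionSpec(pLickCsPlus = pr$behavior$pPlus,
                                    pLickCsMinus = pr$behavior$pMinus,
                                    gradedLicks = TRUE),
                        animalId = id, groupLabel = grp)
      f <- file.path(dir, "sessions", paste0(id, ".csv"))
      writeSessionCsv(ses, f)
      sessions <- c(sessions, basename(f))
    }
  }
  manifest <- list(seed = seed, cells = cells, sessions = sessions)
  jsonlite::write_json(manifest, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.cellIntrinsics <- function(cellDir) {
  out <- list()
  p <- function(sub) file.path(cellDir, sub)
  if (dir.exists(p("vc"))) {
    vc <- readSweepSet(p("vc"))
    qc <- seriesResistanceQc(vc)
    out$rs <- qc$rsMean
    out$rsQcPass <- qc$qcPass
    out$cm <- membraneCapacitance(vc)$cm
  }
  if (dir.exists(p("rin"))) out$rin <- inputResistance(readSweepSet(p("rin")))
  if (dir.exists(p("tau"))) out$tau <- membraneTimeConstant(readSweepSet(p("tau")))
  if (dir.exists(p("sag"))) out$sagPercent <- sagRatio(readSweepSet(p("sag")))$summary
  if (dir.exists(p("fi"))) {
    fc <- fiCurve(readSweepSet(p("fi")))
    out$gain <- fc$gain
  }
  if (dir.exists(p("rheo"))) {
    rh <- readSweepSet(p("rheo"))
    out$rheobase <- rheobase(rh)
    ord <- order(rh@protocol$amplitude)
    minIdx <- ord[which(rh@protocol$amplitude[ord] == out$rheobase)][1]
    ap <- apFeatures(getSweep(rh, minIdx))
    out$apThreshold <- ap$threshold
    out$apAmplitude <- ap$amplitude
    out$apOvershoot <- ap$overshoot
    out$apHalfWidth <- ap$halfWidth
    out$fahp <- ap$fahp
    out$apLatency <- ap$latency
  }
  out
}

#' Run the full analysis pipeline over a fixture directory
#'
#' Reads a dataset written by [makeDemoDataset()] (or assembled in the same
#' layout), computes per-cell intrinsic properties and PSC event tables,
#' compares event-property distributions between the two groups with the
#' balanced-bootstrap permutation KS test, scores the behavioural sessions
#' (block performance and first/last-window ROC), and writes CSV tables, a
#' JSON statistics report and a reproducibility manifest to `outDir`.
#' Per-cell failures are logged and skipped, not fatal. Re-running with the
#' same config and seed reproduces every table byte for byte.
#'
#' @param config list (or path to a JSON file) with `inputDir`, `outDir`, and
#'   optionally `seed` (default 1), `ksIterations`, `ksPermutations`
#'   (default 200 each), `polarity`, `rocWindowTrials` (default 60).
#' @return list with the intrinsic table, event summary, KS results,
#'   behavioural summaries and the log, invisibly; files under `outDir`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(!is.null(config$inputDir), !is.null(config$outDir))
  if (!dir.exists(config$inputDir))
    stop("input directory does not exist: ", config$inputDir)
  if (!file.exists(file.path(config$inputDir, "dataset.json")))
    stop("no dataset.json in ", config$inputDir)
  seed <- config$seed %||% 1L
  ksIter <- config$ksIterations %||% 200L
  ksPerm <- config$ksPermutations %||% 200L
  polarity <- config$polarity %||% "inward"
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ds <- jsonlite::read_json(file.path(config$inputDir, "dataset.json"),
                            simplifyVector = FALSE)
  log <- character(0)

  ## ---- per-cell intrinsic + event measurements --------------------------
  intrinsic <- list()
  eventRows <- list()
  trains <- list()
  for (cell in ds$cells) {
    cellDir <- file.path(config$inputDir, "cells", cell$id)
    res <- tryCatch({
      vals <- .cellIntrinsics(cellDir)
      c(list(cellId = cell$id, group = cell$group), vals)
    }, error = function(e) {
      log <<- c(log, sprintf("intrinsics %s: %s", cell$id,
                             conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) intrinsic[[cell$id]] <- res
    pscDir <- file.path(cellDir, "psc")
    if (dir.exists(pscDir)) {
      tryCatch({
        tr <- getSweep(readSweepSet(pscDir), 1L)
        ev <- detectPscEvents(tr, polarity = polarity)
        if (nrow(ev)) {
          ev$cellId <- cell$id
          ev$group <- cell$group
          eventRows[[cell$id]] <- ev
        }
        trains[[cell$id]] <- buildEventTrain(ev, cell$id, cell$group)
      }, error = function(e)
        log <<- c(log, sprintf("events %s: %s", cell$id,
                               conditionMessage(e))))
    }
  }
  fill <- function(lst) {
    cols <- unique(unlist(lapply(lst, names)))
    do.call(rbind, lapply(lst, function(r) {
      r[setdiff(cols, names(r))] <- NA
      as.data.frame(r[cols])
    }))
  }
  intrinsicDf <- if (length(intrinsic)) fill(intrinsic) else data.frame()
  eventsDf <- if (length(eventRows)) do.call(rbind, eventRows) else data.frame()
  write.csv(intrinsicDf, file.path(outDir, "intrinsic.csv"), row.names = FALSE)
  write.csv(eventsDf, file.path(outDir, "events.csv"), row.names = FALSE)

  summaryDf <- do.call(rbind, lapply(trains, function(tn) {
    ev <- tn$events
    data.frame(cellId = tn$cellId, group = tn$groupLabel,
               nAccepted = tn$nAccepted,
               meanAmplitude = if (nrow(ev)) mean(ev$peakAmplitude) else NA,
               meanRise = if (nrow(ev)) mean(ev$riseTime1090) else NA,
               meanDecay = if (nrow(ev)) mean(ev$decayTau) else NA,
               frequency = tn$meanFrequency)
  }))
  if (!is.null(summaryDf))
    write.csv(summaryDf, file.path(outDir, "event_summary.csv"),
              row.names = FALSE)

  ## ---- group distribution comparisons -----------------------------------
  ksReport <- list()
  groups <- unique(vapply(trains, `[[`, "", "groupLabel"))
  if (length(groups) == 2L) {
    byGroup <- function(fun) lapply(groups, function(g) {
      vals <- lapply(trains[vapply(trains, `[[`, "", "groupLabel") == g], fun)
      vals[lengths(vals) > 0L]
    })
    props <- list(
      amplitude = byGroup(function(tn) tn$events$peakAmplitude),
      iei = byGroup(function(tn) tn$iei))
    for (propName in names(props)) {
      pc <- props[[propName]]
      if (length(pc[[1]]) >= 2L && length(pc[[2]]) >= 2L) {
        res <- tryCatch(
          permutationKs(pc[[1]], pc[[2]], iterations = ksIter,
                        nPermutations = ksPerm, seed = seed),
          error = function(e) {
            log <<- c(log, sprintf("ks %s: %s", propName,
                                   conditionMessage(e)))
            NULL
          })
        if (!is.null(res))
          ksReport[[propName]] <- list(
            groups = groups, observedMeanD = res@observedMeanD,
            observedSdD = res@observedSdD, pValue = res@pValue,
            nPermutations = res@nPermutations, nIterations = res@nIterations)
      }
    }
  }
  jsonlite::write_json(ksReport, file.path(outDir, "ks_report.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- behaviour ---------------------------------------------------------
  blockRows <- list()
  rocRows <- list()
  for (f in ds$sessions) {
    path <- file.path(config$inputDir, "sessions", f)
    tryCatch({
      ses <- readSessionCsv(path)
      bp <- blockPerformance(ses)
      df <- bp$blocks
      df$animalId <- ses@animalId
      df$group <- ses@groupLabel
      df$criterionReached <- bp$criterionReached
      blockRows[[f]] <- df
      for (w in c("first60", "last60")) {
        roc <- rocCurve(ses, w, windowTrials = config$rocWindowTrials %||% 60)
        rocRows[[paste(f, w)]] <- data.frame(
          animalId = ses@animalId, group = ses@groupLabel, window = w,
          auc = roc@auc, seAuc = roc@seAuc, nPos = roc@nPos, nNeg = roc@nNeg)
      }
    }, error = function(e)
      log <<- c(log, sprintf("session %s: %s", f, conditionMessage(e))))
  }
  blocksDf <- if (length(blockRows)) do.call(rbind, blockRows) else data.frame()
  rocDf <- if (length(rocRows)) do.call(rbind, rocRows) else data.frame()
  write.csv(blocksDf, file.path(outDir, "behavior_blocks.csv"),
            row.names = FALSE)
  write.csv(rocDf, file.path(outDir, "behavior_roc.csv"), row.names = FALSE)

  manifest <- list(
    package = "ephysflow",
    version = as.character(utils::packageVersion("ephysflow")),
    seed = seed, config = config[setdiff(names(config), "outDir")],
    nCells = length(ds$cells), nSessions = length(ds$sessions),
    log = log)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(intrinsic = intrinsicDf, events = eventsDf,
                 eventSummary = summaryDf, ks = ksReport, blocks = blocksDf,
                 roc = rocDf, log = log))
}
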