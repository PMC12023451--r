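## Fixture IO. Native format: a directory of per-sweep CSV files plus a JSON
## metadata sidecar declaring dt, units and protocol. Samples are written with
## 17 significant digits so a write -> read round trip is bit exact.

.unitsFor <- function(kind) if (kind == "cc_voltage") "mV" else "pA"

#' Write a SweepSet to a fixture directory
#'
#' Creates `metadata.json` (dt, units, signal kind, protocol, LJP state,
#' cell/group metadata) plus `sweep_001.csv`, `sweep_002.csv`, ... with one
#' sample column each. A ground-truth table attached by a generator is saved
#' as `ground_truth.csv`; scalar ground truth goes into the sidecar.
#'
#' @param x a [SweepSet-class] or single [Trace-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSweepSet <- function(x, dir) {
  if (is(x, "Trace")) {
    x <- SweepSet(matrix(x@samples, ncol = 1), dt = x@dt,
                  signalKind = x@signalKind,
                  protocol = data.frame(amplitude = x@stimAmplitude,
                                        onset = x@stimOnset,
                                        duration = x@stimDuration),
                  ljpApplied = x@ljpApplied, cellId = x@cellId,
                  groupLabel = x@groupLabel, temperature = x@temperature,
                  meta = x@meta)
  }
  stopifnot(is(x, "SweepSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "ephysflow-sweepset-v1",
               dt = x@dt, units = .unitsFor(x@signalKind),
               signal_kind = x@signalKind, n_sweeps = ncol(x@samples),
               protocol = x@protocol, ljp_applied = x@ljpApplied,
               cell_id = x@cellId, group_label = x@groupLabel,
               temperature = x@temperature)
  truth <- x@meta$truth
  if (is.data.frame(truth)) {
    ## full precision so the round trip is exact
    out <- truth
    for (cn in names(out))
      if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
    write.csv(out, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  } else if (!is.null(truth)) {
    meta$truth <- truth
  }
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (i in seq_len(ncol(x@samples))) {
    f <- file.path(dir, sprintf("sweep_%03d.csv", i))
    writeLines(c("sample", sprintf("%.17g", x@samples[, i])), f)
  }
  invisible(dir)
}

#' Read a SweepSet from a fixture directory
#'
#' @param dir directory written by [writeSweepSet()] (or assembled by hand in
#'   the same layout). Missing `dt` or `units` in the sidecar, or units that
#'   disagree with the declared signal kind, raise a format error -- units
#'   are never silently assumed.
#' @return a [SweepSet-class].
#' @export
readSweepSet <- function(dir) {
  metaPath <- file.path(dir, "metadata.json")
  if (!file.exists(metaPath)) stop("format error: no metadata.json in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$dt)) stop("format error: metadata lacks dt")
  if (is.null(meta$units)) stop("format error: metadata lacks units")
  if (is.null(meta$signal_kind)) stop("format error: metadata lacks signal_kind")
  if (!meta$signal_kind %in% c("cc_voltage", "vc_current"))
    stop("format error: unknown signal_kind '", meta$signal_kind, "'")
  if (meta$units != .unitsFor(meta$signal_kind))
    stop("format error: units '", meta$units, "' do not match signal kind '",
         meta$signal_kind, "'")
  nSw <- meta$n_sweeps
  cols <- vector("list", nSw)
  for (i in seq_len(nSw)) {
    f <- file.path(dir, sprintf("sweep_%03d.csv", i))
    if (!file.exists(f)) stop("format error: missing ", basename(f))
    cols[[i]] <- as.numeric(readLines(f)[-1])
  }
  mat <- do.call(cbind, cols)
  metaList <- list()
  truthCsv <- file.path(dir, "ground_truth.csv")
  if (file.exists(truthCsv)) {
    metaList$truth <- read.csv(truthCsv)
  } else if (!is.null(meta$truth)) {
    metaList$truth <- meta$truth
  }
  SweepSet(mat, dt = meta$dt, signalKind = meta$signal_kind,
           protocol = as.data.frame(meta$protocol),
           ljpApplied = meta$ljp_applied %||% 0,
           cellId = meta$cell_id %||% "cell",
           groupLabel = meta$group_label %||% "NA",
           temperature = meta$temperature %||% NA_real_, meta = metaList)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the liquid-junction-potential correction
#'
#' Shifts current-clamp voltages by `-ljp` and records the correction so it
#' can never be applied twice (the audit contract: every voltage exposed
#' downstream is LJP-corrected exactly once). For voltage-clamp data the
#' holding potential stored in `meta$holdingPotential` is corrected instead.
#'
#' @param x a [Trace-class] or [SweepSet-class].
#' @param ljp liquid junction potential, mV (15 mV for a K-gluconate
#'   internal). `ljp = 0` is the identity.
#' @return the corrected object.
#' @export
applyLjp <- function(x, ljp) {
  stopifnot(is(x, "Trace") || is(x, "SweepSet"))
  if (ljp == 0) return(x)
  if (x@ljpApplied != 0)
    stop("LJP correction already applied (", x@ljpApplied,
         " mV); refusing a second application")
  if (x@signalKind == "cc_voltage") {
    x@samples <- x@samples - ljp
  } else {
    hp <- x@meta$holdingPotential
    if (is.null(hp))
      stop("voltage-clamp data need meta$holdingPotential to correct the LJP")
    x@meta$holdingPotential <- hp - ljp
  }
  x@ljpApplied <- ljp
  x
}

#' Write a go/no-go session log as CSV
#'
#' Columns: `trial_index`, `block`, `cs_label`, `interval_licks`
#' (semicolon-joined 0/1 per 0.5-s interval), `valid_flag`, plus
#' `animal_id`, `group_label`, `day`.
#'
#' @param session a [Session-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSessionCsv <- function(session, path) {
  tr <- session@trials
  df <- data.frame(
    trial_index = tr$trial, block = tr$block, cs_label = tr$csLabel,
    interval_licks = vapply(tr$intervalLicks, paste, "", collapse = ";"),
    valid_flag = as.integer(tr$valid),
    animal_id = session@animalId, group_label = session@groupLabel,
    day = session@day)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a go/no-go session log CSV
#'
#' @param path CSV written by [writeSessionCsv()] (or any file with the same
#'   columns).
#' @return a [Session-class].
#' @export
readSessionCsv <- function(path) {
  df <- read.csv(path, colClasses = c(interval_licks = "character"))
  need <- c("trial_index", "block", "cs_label", "interval_licks", "valid_flag")
  if (!all(need %in% names(df)))
    stop("format error: session CSV needs columns ",
         paste(need, collapse = ", "))
  trials <- data.frame(trial = df$trial_index, block = df$block,
                       csLabel = df$cs_label,
                       valid = as.logical(df$valid_flag))
  trials$intervalLicks <- lapply(strsplit(df$interval_licks, ";", fixed = TRUE),
                                 as.integer)
  Session(trials,
          animalId = if ("animal_id" %in% names(df)) df$animal_id[1] else "animal",
          groupLabel = if ("group_label" %in% names(df)) df$group_label[1] else "NA",
          day = if ("day" %in% names(df)) df$day[1] else 1L)
}
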