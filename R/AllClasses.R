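## Central S4 containers: Trace, SweepSet, Session, and result classes.

#' Trace: a uniformly sampled patch-clamp signal
#'
#' A single recorded (or generated) sweep: current-clamp voltage in mV or
#' voltage-clamp current in pA, sampled at a fixed interval, together with a
#' step-stimulus descriptor and cell/group metadata.
#'
#' @slot samples numeric vector of samples (mV for `cc_voltage`, pA for
#'   `vc_current`).
#' @slot dt sampling interval in seconds (`5e-5` for 20 kHz).
#' @slot signalKind `"cc_voltage"` or `"vc_current"`.
#' @slot stimAmplitude step amplitude: pA (current clamp) or mV (voltage-clamp
#'   command).
#' @slot stimOnset step onset in seconds from sweep start.
#' @slot stimDuration step duration in seconds.
#' @slot ljpApplied liquid-junction-potential correction already applied, mV
#'   (0 means uncorrected).
#' @slot cellId,groupLabel cell identifier and group label (e.g. "WT", "KO").
#' @slot temperature bath temperature, degrees C.
#' @slot meta list of additional metadata; generators attach ground truth
#'   under `meta$truth`.
#' @export
setClass("Trace",
  representation(
    samples = "numeric", dt = "numeric", signalKind = "character",
    stimAmplitude = "numeric", stimOnset = "numeric",
    stimDuration = "numeric", ljpApplied = "numeric",
    cellId = "character", groupLabel = "character",
    temperature = "numeric", meta = "list"),
  prototype(
    dt = 5e-5, signalKind = "cc_voltage", stimAmplitude = 0,
    stimOnset = 0, stimDuration = 0, ljpApplied = 0, cellId = "cell",
    groupLabel = "NA", temperature = 32, meta = list()))

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (seconds)")
  if (!object@signalKind %in% c("cc_voltage", "vc_current"))
    msg <- c(msg, "signalKind must be 'cc_voltage' or 'vc_current'")
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must be non-empty")
  if (length(object@ljpApplied) != 1L)
    msg <- c(msg, "ljpApplied must be a single value (mV)")
  if (length(msg)) msg else TRUE
})

#' SweepSet: ordered sweeps sharing a step protocol
#'
#' Sweeps are the columns of a samples matrix; the protocol data frame has one
#' row per sweep with columns `amplitude` (pA for current clamp, mV for a
#' voltage-clamp command), `onset` (s) and `duration` (s).
#'
#' @slot samples numeric matrix, samples x sweeps.
#' @slot dt sampling interval, s.
#' @slot signalKind `"cc_voltage"` or `"vc_current"` (shared by all sweeps).
#' @slot protocol data.frame with columns amplitude, onset, duration.
#' @slot ljpApplied mV already applied (0 = uncorrected).
#' @slot cellId,groupLabel,temperature,meta as in [Trace-class].
#' @export
setClass("SweepSet",
  representation(
    samples = "matrix", dt = "numeric", signalKind = "character",
    protocol = "data.frame", ljpApplied = "numeric",
    cellId = "character", groupLabel = "character",
    temperature = "numeric", meta = "list"),
  prototype(
    dt = 5e-5, signalKind = "cc_voltage",
    protocol = data.frame(amplitude = numeric(), onset = numeric(),
                          duration = numeric()),
    ljpApplied = 0, cellId = "cell", groupLabel = "NA", temperature = 32,
    meta = list()))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (seconds)")
  if (!object@signalKind %in% c("cc_voltage", "vc_current"))
    msg <- c(msg, "signalKind must be 'cc_voltage' or 'vc_current'")
  need <- c("amplitude", "onset", "duration")
  if (!all(need %in% names(object@protocol)))
    msg <- c(msg, "protocol needs columns amplitude, onset, duration")
  else if (nrow(object@protocol) != ncol(object@samples))
    msg <- c(msg, "protocol must have one row per sweep (column)")
  if (length(msg)) msg else TRUE
})

#' Session: one go/no-go behavioural session
#'
#' @slot trials data.frame with columns `trial` (1-based index), `block`,
#'   `csLabel` ("CS+" or "CS-"), `valid` (logical) and a list column
#'   `intervalLicks` of 0/1 integer vectors (one entry per 0.5-s response
#'   interval).
#' @slot animalId,groupLabel,day session metadata.
#' @slot meta list; generators attach the generating probabilities.
#' @export
setClass("Session",
  representation(trials = "data.frame", animalId = "character",
                 groupLabel = "character", day = "integer", meta = "list"),
  prototype(animalId = "animal", groupLabel = "NA", day = 1L, meta = list()))

setValidity("Session", function(object) {
  tr <- object@trials
  need <- c("trial", "block", "csLabel", "valid", "intervalLicks")
  if (!all(need %in% names(tr)))
    return("trials needs columns trial, block, csLabel, valid, intervalLicks")
  if (!all(tr$csLabel %in% c("CS+", "CS-")))
    return("csLabel values must be 'CS+' or 'CS-'")
  for (b in unique(tr$block)) {
    lab <- tr$csLabel[tr$block == b]
    if (sum(lab == "CS+") != sum(lab == "CS-"))
      return(sprintf("block %s has unequal CS+/CS- counts", b))
  }
  TRUE
})

#' BootCpdResult: balanced-bootstrap averaged cumulative distribution
#'
#' @slot grid evaluation grid (units of the event property).
#' @slot meanCpd pointwise mean of the empirical CDFs over iterations.
#' @slot nIterations,nPerCell,seed bookkeeping of the resampling run.
#' @export
setClass("BootCpdResult",
  representation(grid = "numeric", meanCpd = "numeric",
                 nIterations = "integer", nPerCell = "integer",
                 seed = "integer"))

setValidity("BootCpdResult", function(object) {
  p <- object@meanCpd
  if (length(p) != length(object@grid))
    return("meanCpd and grid lengths differ")
  if (any(p < -1e-12 | p > 1 + 1e-12)) return("meanCpd outside [0, 1]")
  if (any(diff(p) < -1e-12)) return("meanCpd must be non-decreasing")
  TRUE
})

#' PermKsResult: permutation Kolmogorov-Smirnov test outcome
#'
#' @slot observedMeanD,observedSdD mean and SD of the two-sample KS D across
#'   balanced-resample iterations (reported as "D = mean +/- SD").
#' @slot nullD null distribution of the statistic from shuffled data.
#' @slot pValue permutation p-value.
#' @slot nPermutations,nIterations,seed run parameters.
#' @slot shuffleUnit "event" or "cell".
#' @slot pEstimator "add_one" ((b+1)/(m+1)) or "proportion" (b/m).
#' @export
setClass("PermKsResult",
  representation(observedMeanD = "numeric", observedSdD = "numeric",
                 nullD = "numeric", pValue = "numeric",
                 nPermutations = "integer", nIterations = "integer",
                 seed = "integer", shuffleUnit = "character",
                 pEstimator = "character"))

setValidity("PermKsResult", function(object) {
  if (object@observedMeanD < 0 || object@observedMeanD > 1)
    return("observed D must lie in [0, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  TRUE
})

#' RocResult: ROC curve and AUC for a go/no-go trial window
#'
#' @slot points data.frame of (fpr, tpr) pairs, from (0,0) to (1,1).
#' @slot auc area under the curve (trapezoidal rule).
#' @slot seAuc Hanley-McNeil standard error.
#' @slot nPos,nNeg numbers of CS+ and CS- trials in the window.
#' @slot window window label ("first60", "last60", "all", "custom").
#' @export
setClass("RocResult",
  representation(points = "data.frame", auc = "numeric", seAuc = "numeric",
                 nPos = "integer", nNeg = "integer", window = "character"))

setValidity("RocResult", function(object) {
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  p <- object@points
  if (!all(c("fpr", "tpr") %in% names(p)))
    return("points needs columns fpr and tpr")
  if (nrow(p) < 2L || p$fpr[1] != 0 || p$tpr[1] != 0 ||
      p$fpr[nrow(p)] != 1 || p$tpr[nrow(p)] != 1)
    return("ROC points must start at (0,0) and end at (1,1)")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace [%s] %d samples @ %.6g s (%.3g s), cell %s (%s)\n",
              object@signalKind, length(object@samples), object@dt,
              length(object@samples) * object@dt, object@cellId,
              object@groupLabel))
  if (object@stimDuration > 0)
    cat(sprintf("  step: %.4g %s at %.4g s for %.4g s\n", object@stimAmplitude,
                if (object@signalKind == "cc_voltage") "pA" else "mV",
                object@stimOnset, object@stimDuration))
  if (object@ljpApplied != 0)
    cat(sprintf("  LJP-corrected by %.4g mV\n", object@ljpApplied))
})

setMethod("show", "SweepSet", function(object) {
  cat(sprintf("SweepSet [%s] %d sweeps x %d samples @ %.6g s, cell %s (%s)\n",
              object@signalKind, ncol(object@samples), nrow(object@samples),
              object@dt, object@cellId, object@groupLabel))
  amps <- object@protocol$amplitude
  if (length(amps))
    cat(sprintf("  step amplitudes: %s %s\n",
                paste(signif(amps, 4), collapse = ", "),
                if (object@signalKind == "cc_voltage") "pA" else "mV"))
})

setMethod("show", "Session", function(object) {
  tr <- object@trials
  cat(sprintf("Session: animal %s (%s), day %d; %d trials in %d blocks (%d valid)\n",
              object@animalId, object@groupLabel, object@day, nrow(tr),
              length(unique(tr$block)), sum(tr$valid)))
})

setMethod("show", "BootCpdResult", function(object) {
  cat(sprintf("BootCpdResult: %d grid points, %d iterations, %d draws/cell\n",
              length(object@grid), object@nIterations, object@nPerCell))
})

setMethod("show", "PermKsResult", function(object) {
  cat(sprintf("Permutation KS: D = %.3f +/- %.3f, p = %.4g (%d permutations, %s shuffle)\n",
              object@observedMeanD, object@observedSdD, object@pValue,
              object@nPermutations, object@shuffleUnit))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("ROC (%s): AUC = %.3f (SE %.3f), n+ = %d, n- = %d\n",
              object@window, object@auc, object@seAuc, object@nPos,
              object@nNeg))
})
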