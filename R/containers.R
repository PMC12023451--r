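## Constructors and accessors for the container classes.

#' Construct a Trace
#'
#' @param samples numeric vector (mV for current clamp, pA for voltage clamp).
#' @param dt sampling interval, s.
#' @param signalKind "cc_voltage" or "vc_current".
#' @param stimAmplitude,stimOnset,stimDuration step descriptor (pA or mV, s, s).
#' @param ljpApplied LJP already applied, mV.
#' @param cellId,groupLabel,temperature metadata.
#' @param meta list of extra metadata (ground truth lives in `meta$truth`).
#' @return a [Trace-class] object.
#' @export
Trace <- function(samples, dt, signalKind = c("cc_voltage", "vc_current"),
                  stimAmplitude = 0, stimOnset = 0, stimDuration = 0,
                  ljpApplied = 0, cellId = "cell", groupLabel = "NA",
                  temperature = 32, meta = list()) {
  new("Trace", samples = as.numeric(samples), dt = dt,
      signalKind = match.arg(signalKind), stimAmplitude = stimAmplitude,
      stimOnset = stimOnset, stimDuration = stimDuration,
      ljpApplied = ljpApplied, cellId = cellId, groupLabel = groupLabel,
      temperature = temperature, meta = meta)
}

#' Construct a SweepSet
#'
#' @param samples numeric matrix, samples x sweeps.
#' @param dt sampling interval, s.
#' @param signalKind "cc_voltage" or "vc_current".
#' @param protocol data.frame with columns amplitude, onset, duration (one row
#'   per sweep).
#' @param ljpApplied,cellId,groupLabel,temperature,meta metadata.
#' @return a [SweepSet-class] object.
#' @export
SweepSet <- function(samples, dt, signalKind = c("cc_voltage", "vc_current"),
                     protocol, ljpApplied = 0, cellId = "cell",
                     groupLabel = "NA", temperature = 32, meta = list()) {
  new("SweepSet", samples = as.matrix(samples), dt = dt,
      signalKind = match.arg(signalKind), protocol = protocol,
      ljpApplied = ljpApplied, cellId = cellId, groupLabel = groupLabel,
      temperature = temperature, meta = meta)
}

#' Construct a Session
#'
#' @param trials data.frame with columns trial, block, csLabel, valid, and a
#'   list column intervalLicks of 0/1 integer vectors.
#' @param animalId,groupLabel,day,meta metadata.
#' @return a [Session-class] object.
#' @export
Session <- function(trials, animalId = "animal", groupLabel = "NA", day = 1L,
                    meta = list()) {
  new("Session", trials = trials, animalId = animalId,
      groupLabel = groupLabel, day = as.integer(day), meta = meta)
}

## ---- generics + accessors ------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))
#' @rdname accessors
#' @export
setGeneric("sweepMatrix", function(x) standardGeneric("sweepMatrix"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("signalKind", function(x) standardGeneric("signalKind"))
#' @rdname accessors
#' @export
setGeneric("protocolTable", function(x) standardGeneric("protocolTable"))
#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("getSweep", function(x, i) standardGeneric("getSweep"))
#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("meanCpd", function(x) standardGeneric("meanCpd"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Accessors for ephysflow containers
#'
#' `nSweeps`, `sweepMatrix`, `samplingInterval`, `signalKind`,
#' `protocolTable`, `cellId`, `groupLabel`, `traceSamples`, `groundTruth`,
#' `getSweep`, `trialTable`, `aucValue`, `meanCpd`, `pValue` expose slots of
#' the container and result classes without touching `@`.
#'
#' @param x a container or result object.
#' @param i sweep index for `getSweep`.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nSweeps", "SweepSet", function(x) ncol(x@samples))
#' @rdname accessors
setMethod("sweepMatrix", "SweepSet", function(x) x@samples)
#' @rdname accessors
setMethod("samplingInterval", "SweepSet", function(x) x@dt)
#' @rdname accessors
setMethod("samplingInterval", "Trace", function(x) x@dt)
#' @rdname accessors
setMethod("signalKind", "SweepSet", function(x) x@signalKind)
#' @rdname accessors
setMethod("signalKind", "Trace", function(x) x@signalKind)
#' @rdname accessors
setMethod("protocolTable", "SweepSet", function(x) x@protocol)
#' @rdname accessors
setMethod("cellId", "SweepSet", function(x) x@cellId)
#' @rdname accessors
setMethod("cellId", "Trace", function(x) x@cellId)
#' @rdname accessors
setMethod("groupLabel", "SweepSet", function(x) x@groupLabel)
#' @rdname accessors
setMethod("groupLabel", "Trace", function(x) x@groupLabel)
#' @rdname accessors
setMethod("traceSamples", "Trace", function(x) x@samples)
#' @rdname accessors
setMethod("groundTruth", "Trace", function(x) x@meta$truth)
#' @rdname accessors
setMethod("groundTruth", "SweepSet", function(x) x@meta$truth)
#' @rdname accessors
setMethod("getSweep", "SweepSet", function(x, i) {
  stopifnot(i >= 1L, i <= ncol(x@samples))
  p <- x@protocol[i, ]
  Trace(x@samples[, i], dt = x@dt, signalKind = x@signalKind,
        stimAmplitude = p$amplitude, stimOnset = p$onset,
        stimDuration = p$duration, ljpApplied = x@ljpApplied,
        cellId = x@cellId, groupLabel = x@groupLabel,
        temperature = x@temperature, meta = x@meta)
})
#' @rdname accessors
setMethod("trialTable", "Session", function(x) x@trials)
#' @rdname accessors
setMethod("aucValue", "RocResult", function(x) x@auc)
#' @rdname accessors
setMethod("meanCpd", "BootCpdResult", function(x) x@meanCpd)
#' @rdname accessors
setMethod("pValue", "PermKsResult", function(x) x@pValue)

## time axis helper, 0-based from sweep start
timeAxis <- function(n, dt) (seq_len(n) - 1) * dt
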