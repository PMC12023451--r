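## Spontaneous postsynaptic-current detection and characterisation.
##
## Pipeline: binomial smoothing (25 coefficients) -> candidate peaks scored
## against a local "previous baseline" (5 pA and 2.5 x SD rules) -> kinetics
## on the raw trace (10-90% rise, single-exponential decay fit) -> kinetic
## rejection rules (decay >= 1 ms and decay >= rise). Detection operates on a
## sign-rectified copy (inward events become positive deflections); reported
## amplitudes are positive magnitudes.

#' Binomial smoothing
#'
#' Convolution with the unit-sum binomial kernel `C(n-1, k)/2^(n-1)`
#' (25 coefficients by default), length-preserving via symmetric edge
#' reflection.
#'
#' @param x numeric vector or a [Trace-class].
#' @param nCoef number of kernel coefficients (odd).
#' @return smoothed object of the same type as `x`.
#' @export
binomialSmooth <- function(x, nCoef = 25) {
  if (is(x, "Trace")) {
    x@samples <- binomialSmooth(x@samples, nCoef)
    return(x)
  }
  stopifnot(nCoef %% 2 == 1)
  if (length(x) < nCoef)
    stop("trace shorter than the smoothing kernel (", nCoef, " samples)")
  kern <- binomialKernel(nCoef)
  h <- (nCoef - 1L) / 2L
  padded <- c(rev(x[seq_len(h) + 1L]), x, rev(x[length(x) - seq_len(h)]))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(h + 1L):(h + length(x))])
}

#' @rdname binomialSmooth
#' @return `binomialKernel`: the kernel weights (sum to 1, symmetric).
#' @export
binomialKernel <- function(nCoef = 25) {
  choose(nCoef - 1L, 0:(nCoef - 1L)) / 2^(nCoef - 1L)
}

## local maxima of y (strict on the right to break plateau ties)
.localMaxima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

#' Detect candidate synaptic events
#'
#' Smooths the rectified trace, locates local maxima, and scores each peak's
#' deflection against the mean of the preceding baseline (a 10-ms window
#' ending 1 ms before onset, excluding samples of prior events when enough
#' clean samples exist). Peaks whose deflection fails the amplitude threshold
#' (5 pA) or the SD rule (2.5 x baseline SD, with the SD measured on the raw
#' trace) are returned with status `rejected_amplitude`; the rest are
#' `candidate`s. Onset is the last baseline crossing before the peak.
#'
#' @param trace a voltage-clamp [Trace-class].
#' @param polarity "inward" or "outward"; defaults to the generator's
#'   polarity when present in the trace metadata, else "inward".
#' @param ampThreshold amplitude threshold, pA.
#' @param sdMultiplier baseline-SD multiple an event must exceed.
#' @param baselineMs,baselineGapMs baseline window length and its gap before
#'   onset, ms.
#' @param nCoef binomial smoothing coefficients.
#' @return data.frame with columns peakIdx, onsetIdx, onsetTime, peakTime,
#'   deflection (pA), baselineMean (rectified pA), baselineSd (pA), status.
#' @export
detectCandidates <- function(trace, polarity = NULL, ampThreshold = 5,
                             sdMultiplier = 2.5, baselineMs = 10,
                             baselineGapMs = 1, nCoef = 25) {
  stopifnot(is(trace, "Trace"))
  if (trace@signalKind != "vc_current")
    stop("event detection needs a voltage-clamp current trace")
  if (is.null(polarity))
    polarity <- trace@meta$spec$polarity %||% "inward"
  sgn <- if (polarity == "inward") -1 else 1
  r <- sgn * trace@samples
  y <- binomialSmooth(r, nCoef)
  dt <- trace@dt
  n <- length(y)

  bLen <- max(2L, round(baselineMs * 1e-3 / dt))
  bGap <- max(1L, round(baselineGapMs * 1e-3 / dt))
  mergeWin <- max(1L, round(1e-3 / dt))
  onsetSearch <- max(1L, round(20e-3 / dt))

  ## cheap pre-filter against the global median before exact local baselines
  peaks <- .localMaxima(y)
  gBase <- median(y)
  gSd <- sd(r - y)
  bar <- min(0.6 * ampThreshold, 2 * max(gSd, 1e-12))
  peaks <- peaks[y[peaks] - gBase >= 0.8 * bar]
  peaks <- peaks[peaks > bLen + bGap + 1L]
  ## merge peaks closer than 1 ms, keeping the larger
  if (length(peaks) > 1L) {
    keep <- logical(length(peaks))
    cur <- 1L
    for (i in seq_along(peaks)[-1]) {
      if (peaks[i] - peaks[cur] <= mergeWin) {
        if (y[peaks[i]] > y[peaks[cur]]) cur <- i
      } else {
        keep[cur] <- TRUE
        cur <- i
      }
    }
    keep[cur] <- TRUE
    peaks <- peaks[keep]
  }

  mask <- logical(n)
  gSdRaw <- sd(r - y)            # high-frequency noise SD from the residual
  lastPeak <- NA_integer_
  rows <- vector("list", length(peaks))
  nOut <- 0L
  for (ip in peaks) {
    if (mask[ip] && !is.na(lastPeak)) {
      ## peak rides on the decay of a previous event: score the local rise
      ## from the valley between the two peaks against the decaying baseline
      win <- (lastPeak + 1L):(ip - 1L)
      if (length(win) < 2L) next
      vIdx <- win[which.min(y[win])]
      vWin <- max(win[1], vIdx - mergeWin %/% 2L):min(ip - 1L, vIdx + mergeWin %/% 2L)
      bMean <- mean(y[vWin])
      bSd <- gSdRaw
      onset <- vIdx
    } else {
      localBase <- function(endIdx) {
        win <- max(1L, endIdx - bGap - bLen + 1L):max(1L, endIdx - bGap)
        clean <- win[!mask[win]]
        use <- if (length(clean) >= max(10L, bLen %/% 4L)) clean else win
        c(mean(y[use]), sd(r[use]))
      }
      bs <- localBase(ip)
      ## onset: last crossing of the baseline mean before the peak
      lo <- max(1L, ip - onsetSearch)
      below <- lo - 1L + which(y[lo:ip] <= bs[1])
      onset <- if (length(below)) max(below) else lo
      bs <- localBase(onset)         # refine: window ends 1 ms before onset
      below <- lo - 1L + which(y[lo:ip] <= bs[1])
      onset <- if (length(below)) max(below) else lo
      bMean <- bs[1]
      bSd <- bs[2]
    }
    defl <- y[ip] - bMean
    if (defl < bar) next             # below the discovery floor
    status <- if (defl < ampThreshold || defl < sdMultiplier * bSd)
      "rejected_amplitude" else "candidate"
    if (status == "candidate") {
      ## mask the event span so later baselines can exclude it
      span <- ip:min(n, ip + onsetSearch)
      recov <- span[y[span] <= bMean + 0.1 * defl]
      mask[onset:(if (length(recov)) recov[1] else max(span))] <- TRUE
      lastPeak <- ip
    }
    nOut <- nOut + 1L
    rows[[nOut]] <- data.frame(
      peakIdx = ip, onsetIdx = onset, onsetTime = (onset - 1L) * dt,
      peakTime = (ip - 1L) * dt, deflection = defl, baselineMean = bMean,
      baselineSd = bSd, status = status)
  }
  if (nOut == 0L)
    return(data.frame(peakIdx = integer(0), onsetIdx = integer(0),
                      onsetTime = numeric(0), peakTime = numeric(0),
                      deflection = numeric(0), baselineMean = numeric(0),
                      baselineSd = numeric(0), status = character(0)))
  do.call(rbind, rows[seq_len(nOut)])
}

#' Characterise one candidate event on the raw trace
#'
#' 10-90% rise time by linear interpolation between the level crossings, and
#' decay time constant by a least-squares single exponential fitted on the
#' raw (unsmoothed) trace from shortly after the peak to 90% recovery
#' (truncated at the next candidate's onset). Kinetic rejection rules are
#' applied: fitted decay < 1 ms or shorter than the rise time rejects the
#' event.
#'
#' @param trace the voltage-clamp [Trace-class] (raw).
#' @param candidate one row of [detectCandidates()] output.
#' @param polarity "inward" or "outward".
#' @param decayFitOffsetMs delay after the peak before the decay fit starts,
#'   ms (skips the residual rising component of the biexponential shape).
#' @param nextOnsetIdx onset index of the following candidate (truncates the
#'   decay window), or NA.
#' @return one-row data.frame with onsetTime, peakTime, peakAmplitude,
#'   riseTime1090 (ms), decayTau (ms), baselineMean (original sign, pA),
#'   baselineSd (pA), status.
#' @export
characterizeEvent <- function(trace, candidate, polarity = NULL,
                              decayFitOffsetMs = 1, nextOnsetIdx = NA) {
  stopifnot(is(trace, "Trace"))
  if (is.null(polarity))
    polarity <- trace@meta$spec$polarity %||% "inward"
  sgn <- if (polarity == "inward") -1 else 1
  r <- sgn * trace@samples
  dt <- trace@dt
  n <- length(r)
  ip <- candidate$peakIdx
  onset <- candidate$onsetIdx
  b <- candidate$baselineMean
  amp <- candidate$deflection

  out <- data.frame(onsetTime = candidate$onsetTime,
                    peakTime = candidate$peakTime, peakAmplitude = amp,
                    riseTime1090 = NA_real_, decayTau = NA_real_,
                    baselineMean = sgn * b, baselineSd = candidate$baselineSd,
                    status = candidate$status)
  if (candidate$status != "candidate") return(out)

  ## ---- 10-90% rise on the raw trace -------------------------------------
  l10 <- b + 0.1 * amp
  l90 <- b + 0.9 * amp
  seg <- onset:ip
  i90 <- seg[which(r[seg] >= l90)[1]]
  if (is.na(i90)) i90 <- ip
  pre <- seg[seg < i90]
  below10 <- pre[r[pre] <= l10]
  i10 <- if (length(below10)) max(below10) else onset
  interp <- function(i, level) {
    if (i >= n || r[i + 1L] == r[i]) return((i - 1L) * dt)
    (i - 1L + (level - r[i]) / (r[i + 1L] - r[i])) * dt
  }
  t10 <- interp(i10, l10)
  t90 <- interp(max(i90 - 1L, i10), l90)
  rise <- max((t90 - t10) * 1000, dt * 1000)

  ## ---- single-exponential decay fit on the raw trace --------------------
  start <- ip + max(1L, round(decayFitOffsetMs * 1e-3 / dt))
  ySm <- candidate$deflection
  end <- n
  recov <- start - 1L + which(r[start:n] <= b + 0.1 * amp)
  if (length(recov)) end <- recov[1]
  if (!is.na(nextOnsetIdx)) end <- min(end, nextOnsetIdx - 1L)
  end <- min(end, ip + round(0.2 / dt))    # hard cap: 200 ms of decay
  status <- "accepted"
  tau <- NA_real_
  if (end - start < 3L) {
    status <- "rejected_fit"
  } else {
    idx <- start:end
    ydec <- r[idx] - b
    tdec <- (idx - ip) * dt * 1000
    pos <- ydec > 0
    tau <- tryCatch({
      if (sum(pos) < 3L) stop("too few positive samples")
      lf <- lm(log(ydec[pos]) ~ tdec[pos])
      tau0 <- unname(-1 / coef(lf)[2])
      if (!is.finite(tau0) || tau0 <= 0) tau0 <- 2
      fit <- minpack.lm::nlsLM(ydec ~ A * exp(-tdec / tau),
                               start = list(A = amp, tau = tau0),
                               control = minpack.lm::nls.lm.control(maxiter = 100))
      coef(fit)[["tau"]]
    }, error = function(e) NA_real_)
    if (!is.finite(tau) || tau <= 0 || tau > 500) status <- "rejected_fit"
  }
  if (status == "accepted") {
    if (tau < 1) status <- "rejected_decay_lt_1ms"
    else if (tau < rise) status <- "rejected_decay_lt_rise"
  }
  out$riseTime1090 <- rise
  out$decayTau <- tau
  out$status <- status
  out
}

#' Detect and characterise spontaneous PSCs in a trace
#'
#' Runs [detectCandidates()] and [characterizeEvent()] over a voltage-clamp
#' recording. Accepted events satisfy all of: peak amplitude >= `ampThreshold`
#' (5 pA), >= `sdMultiplier` (2.5) x baseline SD, fitted decay >= 1 ms, and
#' decay >= 10-90% rise time. Rejected events carry exactly one rejection
#' reason.
#'
#' @inheritParams detectCandidates
#' @inheritParams characterizeEvent
#' @return data.frame of events (accepted and rejected) ordered by onset,
#'   with the columns of [characterizeEvent()].
#' @export
detectPscEvents <- function(trace, polarity = NULL, ampThreshold = 5,
                            sdMultiplier = 2.5, baselineMs = 10,
                            baselineGapMs = 1, nCoef = 25,
                            decayFitOffsetMs = 1) {
  cand <- detectCandidates(trace, polarity, ampThreshold, sdMultiplier,
                           baselineMs, baselineGapMs, nCoef)
  if (!nrow(cand))
    return(data.frame(onsetTime = numeric(0), peakTime = numeric(0),
                      peakAmplitude = numeric(0), riseTime1090 = numeric(0),
                      decayTau = numeric(0), baselineMean = numeric(0),
                      baselineSd = numeric(0), status = character(0)))
  nxt <- c(cand$onsetIdx[-1], NA)
  rows <- lapply(seq_len(nrow(cand)), function(i)
    characterizeEvent(trace, cand[i, ], polarity,
                      decayFitOffsetMs = decayFitOffsetMs,
                      nextOnsetIdx = nxt[i]))
  do.call(rbind, rows)
}

#' Build an event train from detected events
#'
#' Keeps accepted events, computes inter-event intervals between consecutive
#' onsets, and the mean frequency as the inverse of the mean inter-event
#' interval. Cells with fewer than two accepted events get an undefined
#' frequency and are flagged.
#'
#' @param events data.frame from [detectPscEvents()] (or a ground-truth table
#'   with `onsetTime`).
#' @param cellId,groupLabel cell metadata.
#' @return list with cellId, groupLabel, events (accepted), iei (s),
#'   meanFrequency (Hz or NA), frequencyDefined, nAccepted.
#' @export
buildEventTrain <- function(events, cellId = "cell", groupLabel = "NA") {
  acc <- if ("status" %in% names(events))
    events[events$status == "accepted", , drop = FALSE] else events
  acc <- acc[order(acc$onsetTime), , drop = FALSE]
  iei <- diff(acc$onsetTime)
  freq <- if (length(iei) >= 1L) 1 / mean(iei) else NA_real_
  list(cellId = cellId, groupLabel = groupLabel, events = acc, iei = iei,
       meanFrequency = freq, frequencyDefined = is.finite(freq),
       nAccepted = nrow(acc))
}
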