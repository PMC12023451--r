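## Synthetic voltage-clamp recordings: Gaussian baseline noise plus linearly
## superposed biexponential synaptic events at Poisson onset times.

#' Unit-peak biexponential PSC kernel
#'
#' `(exp(-t/decayTau) - exp(-t/riseTau))`, normalised so the peak equals 1,
#' evaluated at `tMs >= 0` (0 elsewhere).
#'
#' @param tMs time from event onset, ms (vector).
#' @param riseTau,decayTau kernel time constants, ms (`decayTau > riseTau`).
#' @return numeric vector, peak value 1.
#' @export
pscKernel <- function(tMs, riseTau, decayTau) {
  stopifnot(decayTau > riseTau, riseTau > 0)
  tPeak <- riseTau * decayTau / (decayTau - riseTau) * log(decayTau / riseTau)
  norm <- exp(-tPeak / decayTau) - exp(-tPeak / riseTau)
  out <- numeric(length(tMs))
  pos <- tMs >= 0
  out[pos] <- (exp(-tMs[pos] / decayTau) - exp(-tMs[pos] / riseTau)) / norm
  out
}

.drawAmplitudes <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  switch(dist$name,
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    normal = pmax(rnorm(n, dist$mean, dist$sd), 1),
    uniform = runif(n, dist$min, dist$max),
    constant = rep(dist$value, n),
    stop("unknown amplitude distribution: ", dist$name))
}

#' Generate a synthetic spontaneous-PSC recording with ground truth
#'
#' Baseline Gaussian noise plus a linear superposition of unit-peak
#' biexponential kernels scaled by amplitudes drawn from the configured
#' distribution, inserted at Poisson onset times. Inward polarity deflects
#' the trace negative; ground-truth amplitudes are positive magnitudes.
#'
#' @param spec an [EventGenSpec-class] object.
#' @param dt sampling interval, s.
#' @param seed optional integer seed (same seed, same trace bit-for-bit).
#' @param cellId,groupLabel metadata.
#' @return a [Trace-class] (`signalKind = "vc_current"`); `groundTruth()`
#'   returns a data.frame with columns onset (s), amplitude (pA), riseTau and
#'   decayTau (ms), ordered by onset.
#' @export
genSynapticTrace <- function(spec, dt = 5e-5, seed = NULL, cellId = "cell",
                             groupLabel = "NA") {
  stopifnot(is(spec, "EventGenSpec"))
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)

  n <- round(spec@duration / dt)
  cur <- rnorm(n, spec@baselineMean, spec@baselineNoiseSd)

  nEv <- rpois(1, spec@rate * spec@duration)
  onsets <- sort(runif(nEv, 0, spec@duration))
  amps <- .drawAmplitudes(spec@amplitudeDist, nEv)
  sgn <- if (spec@polarity == "inward") -1 else 1

  if (nEv > 0) {
    kernelLen <- min(round(20 * spec@decayTau * 1e-3 / dt), n)
    for (e in seq_len(nEv)) {
      i0 <- floor(onsets[e] / dt) + 1L
      i1 <- min(i0 + kernelLen, n)
      tMs <- (timeAxis(n, dt)[i0:i1] - onsets[e]) * 1000
      cur[i0:i1] <- cur[i0:i1] +
        sgn * amps[e] * pscKernel(tMs, spec@riseTau, spec@decayTau)
    }
  }

  truth <- data.frame(onset = onsets, amplitude = amps,
                      riseTau = rep(spec@riseTau, nEv),
                      decayTau = rep(spec@decayTau, nEv))
  Trace(cur, dt = dt, signalKind = "vc_current", cellId = cellId,
        groupLabel = groupLabel,
        meta = list(truth = truth,
                    spec = list(rate = spec@rate, riseTau = spec@riseTau,
                                decayTau = spec@decayTau,
                                polarity = spec@polarity,
                                baselineMean = spec@baselineMean,
                                baselineNoiseSd = spec@baselineNoiseSd)))
}
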