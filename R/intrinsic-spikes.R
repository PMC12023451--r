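## Spike detection, F-I curves, rheobase and phase-plot AP features.

#' Detect action potentials by 0-mV crossing
#'
#' One spike per upward 0-mV crossing, with spikes closer than the refractory
#' window merged into one; spike times are reported at the peak.
#'
#' @param x a current-clamp [Trace-class] or a numeric voltage vector.
#' @param dt sampling interval, s (taken from the Trace when given).
#' @param threshold crossing level, mV.
#' @param refractoryMs minimum separation between detections, ms.
#' @return spike times in seconds (possibly empty).
#' @export
detectSpikes <- function(x, dt = NULL, threshold = 0, refractoryMs = 1) {
  if (is(x, "Trace")) {
    if (x@signalKind != "cc_voltage")
      stop("spike detection needs a current-clamp voltage trace")
    dt <- x@dt
    v <- x@samples
  } else {
    v <- as.numeric(x)
    if (is.null(dt)) stop("dt is required for a bare numeric trace")
  }
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  peakWin <- max(1L, round(2e-3 / dt))
  times <- vapply(up, function(i) {
    j <- i:min(i + peakWin, length(v))
    (j[which.max(v[j])] - 1L) * dt
  }, numeric(1))
  keep <- times[1]
  for (tt in times[-1])
    if (tt - keep[length(keep)] >= refractoryMs * 1e-3) keep <- c(keep, tt)
  keep
}

#' F-I curve: spike counts, frequencies, gain and linear region
#'
#' Counts spikes within each step (25 pA to 1 nA in 50 pA increments in the
#' reference protocol), converts to frequency as `count / duration`, and
#' fits the gain as the regression slope over the first k non-zero points,
#' with k in `kCandidates` chosen by the best linear fit (highest R^2).
#'
#' @param sweeps a current-clamp [SweepSet-class] of depolarizing steps.
#' @param kCandidates candidate numbers of initial non-zero points for the
#'   gain fit.
#' @return list with `fi` (data.frame current/count/frequency, sorted by
#'   current), `gain` (Hz/pA; NA when undefined), `gainDefined`,
#'   `linearRegion` (row indices of `fi` used for the fit), and `rheobase`
#'   (smallest current with a spike at this protocol's resolution; NA if no
#'   sweep spikes).
#' @export
fiCurve <- function(sweeps, kCandidates = 3:4) {
  stopifnot(is(sweeps, "SweepSet"))
  if (sweeps@signalKind != "cc_voltage")
    stop("F-I analysis needs current-clamp sweeps")
  ord <- order(sweeps@protocol$amplitude)
  amps <- sweeps@protocol$amplitude[ord]
  counts <- vapply(ord, function(i) {
    p <- sweeps@protocol[i, ]
    st <- detectSpikes(getSweep(sweeps, i))
    sum(st >= p$onset & st < p$onset + p$duration)
  }, numeric(1))
  dur <- sweeps@protocol$duration[ord]
  fi <- data.frame(current = amps, count = counts, frequency = counts / dur)

  nz <- which(counts > 0)
  gain <- NA_real_
  region <- integer(0)
  if (length(nz) >= 2L) {
    best <- -Inf
    for (k in kCandidates) {
      if (length(nz) < k) next
      idx <- nz[seq_len(k)]
      fit <- lm(frequency ~ current, data = fi[idx, ])
      y <- fi$frequency[idx]
      tss <- sum((y - mean(y))^2)
      r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 0
      if (is.finite(r2) && r2 > best) {
        best <- r2
        gain <- unname(coef(fit)[2])
        region <- idx
      }
    }
    if (!length(region)) {        # fewer non-zero points than any candidate k
      fit <- lm(frequency ~ current, data = fi[nz, ])
      gain <- unname(coef(fit)[2])
      region <- nz
    }
  }
  list(fi = fi, gain = gain, gainDefined = is.finite(gain),
       linearRegion = region,
       rheobase = if (length(nz)) amps[nz[1]] else NA_real_)
}

#' Rheobase from a fine current-step protocol
#'
#' The amplitude of the smallest step (5 pA increments in the reference
#' protocol) eliciting at least one action potential.
#'
#' @param sweeps a current-clamp [SweepSet-class] ordered or orderable by
#'   amplitude, spanning sub- and supra-threshold currents.
#' @return rheobase, pA. Errors if no sweep spikes; warns (and returns the
#'   smallest tested amplitude) if every sweep spikes.
#' @export
rheobase <- function(sweeps) {
  stopifnot(is(sweeps, "SweepSet"))
  ord <- order(sweeps@protocol$amplitude)
  spiking <- vapply(ord, function(i) {
    p <- sweeps@protocol[i, ]
    st <- detectSpikes(getSweep(sweeps, i))
    any(st >= p$onset & st < p$onset + p$duration)
  }, logical(1))
  if (!any(spiking)) stop("no sweep elicited an action potential")
  if (all(spiking))
    warning("all sweeps spike; rheobase is at or below the smallest tested current")
  sweeps@protocol$amplitude[ord][which(spiking)[1]]
}

#' Phase-plot action-potential features of the first evoked spike
#'
#' Threshold is the voltage of the first point where dV/dt (central
#' differences on the raw grid, no smoothing) exceeds `dvdtThreshold`
#' (10 mV/ms); amplitude is threshold to peak; overshoot is the peak value
#' above 0 mV; half-width is measured at half amplitude between the
#' interpolated rising and falling crossings; fAHP is the post-peak minimum
#' minus threshold; latency is stimulus onset to threshold.
#'
#' @param trace a current-clamp [Trace-class] holding the minimal
#'   suprathreshold sweep (the first spike is analysed).
#' @param stimOnset stimulus onset, s (defaults to the trace's step onset).
#' @param dvdtThreshold phase-plot threshold criterion, mV/ms.
#' @param fahpWindowMs window after the peak searched for the fAHP minimum,
#'   ms (truncated at the next spike).
#' @return list with threshold (mV), amplitude (mV), overshoot (mV),
#'   halfWidth (ms), fahp (mV), latency (ms), peak (mV), thresholdTime (s).
#' @export
apFeatures <- function(trace, stimOnset = NULL, dvdtThreshold = 10,
                       fahpWindowMs = 20) {
  stopifnot(is(trace, "Trace"))
  if (trace@signalKind != "cc_voltage")
    stop("AP features need a current-clamp voltage trace")
  v <- trace@samples
  dt <- trace@dt
  if (is.null(stimOnset)) stimOnset <- trace@stimOnset
  st <- detectSpikes(trace)
  st <- st[st >= stimOnset]
  if (!length(st)) stop("no spike in the trace")
  iPk <- round(st[1] / dt) + 1L
  n <- length(v)
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt * 1000), NA)  # mV/ms
  onsetIdx <- max(round(stimOnset / dt) + 1L, 2L)
  seg <- onsetIdx:iPk
  if (!any(dvdt[seg] > dvdtThreshold, na.rm = TRUE))
    stop("dV/dt never exceeds ", dvdtThreshold, " mV/ms before the peak")
  ## first point of the contiguous dV/dt > threshold run containing the
  ## upstroke maximum (a backward search from the fastest upstroke point;
  ## identical to the forward rule on clean upstrokes, but immune to isolated
  ## noise crossings in the baseline)
  iUp <- seg[which.max(dvdt[seg])]
  below <- seg[seg <= iUp & dvdt[seg] <= dvdtThreshold]
  iThr <- if (length(below)) max(below) + 1L else seg[1]
  thr <- v[iThr]
  peak <- v[iPk]
  amplitude <- peak - thr
  overshoot <- if (peak > 0) peak else NA_real_
  half <- thr + amplitude / 2

  interpCross <- function(i, rising) {
    ## linear interpolation of the crossing between samples i-1 and i
    (i - 2 + (half - v[i - 1]) / (v[i] - v[i - 1])) * dt
  }
  riseIdx <- which(v[iThr:iPk] >= half)[1] + iThr - 1L
  tRise <- interpCross(riseIdx, TRUE)
  after <- iPk + which(v[(iPk + 1):n] < half)
  if (!length(after)) stop("voltage never recrosses half amplitude after the peak")
  tFall <- interpCross(after[1], FALSE)
  halfWidth <- (tFall - tRise) * 1000

  fahpEnd <- min(iPk + round(fahpWindowMs * 1e-3 / dt), n)
  if (length(st) > 1) fahpEnd <- min(fahpEnd, round(st[2] / dt))
  fahp <- min(v[iPk:fahpEnd]) - thr
  latency <- ((iThr - 1L) * dt - stimOnset) * 1000

  list(threshold = thr, amplitude = amplitude, overshoot = overshoot,
       halfWidth = halfWidth, fahp = fahp, latency = latency, peak = peak,
       thresholdTime = (iThr - 1L) * dt)
}
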