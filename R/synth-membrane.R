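## Synthetic membrane responses: single-compartment RC with optional sag
## (current clamp) and a two-resistor RC access model (voltage clamp).
## Piecewise closed forms evaluated on the sample grid: for piecewise-constant
## stimuli the exponential update is exact, so noise-free traces match the
## analytic step response to machine precision.

#' Generate passive step-response sweeps with ground truth
#'
#' Current-clamp mode produces voltage responses of a single-compartment RC
#' membrane (time constant `inputResistance * capacitance`) with an optional
#' phenomenological sag: a slow relaxation of the step deflection back toward
#' baseline by a fraction `sagFraction` with time constant `sagTau`.
#' Voltage-clamp mode produces the clamp current of the same membrane accessed
#' through `seriesResistance`, i.e. a fast capacitive transient with initial
#' peak `dV/Rs` decaying to the steady state `dV/(Rs + Rm)`.
#'
#' @param params a [MembraneParams-class] object (ground truth).
#' @param protocol data.frame with columns `amplitude` (pA in "cc", mV command
#'   in "vc"), `onset` (s) and `duration` (s); one row per sweep.
#' @param dt sampling interval, s (default 5e-5, i.e. 20 kHz).
#' @param sweepDuration sweep length, s; default extends 40% of the step past
#'   its offset.
#' @param mode "cc" (current clamp) or "vc" (voltage clamp).
#' @param sagTau slow sag time constant, s.
#' @param seed optional integer seed; the same seed reproduces the sweeps
#'   bit-for-bit.
#' @param cellId,groupLabel metadata attached to the sweeps.
#' @return a [SweepSet-class]; `groundTruth()` returns the generating
#'   parameters.
#' @export
genPassiveStepTraces <- function(params, protocol, dt = 5e-5,
                                 sweepDuration = NULL, mode = c("cc", "vc"),
                                 sagTau = 0.15, seed = NULL,
                                 cellId = "cell", groupLabel = "NA") {
  mode <- match.arg(mode)
  stopifnot(is(params, "MembraneParams"))
  validObject(params)
  .checkProtocol(protocol, dt)
  if (!is.null(seed)) set.seed(seed)

  rin <- params@inputResistance
  cm <- params@capacitance
  rs <- params@seriesResistance
  tauS <- rin * cm * 1e-6            # MOhm * pF = us
  if (mode == "vc" && rs <= 0)
    stop("voltage-clamp mode requires seriesResistance > 0")

  if (is.null(sweepDuration))
    sweepDuration <- max(protocol$onset + 1.4 * protocol$duration)
  n <- round(sweepDuration / dt)
  t <- timeAxis(n, dt)

  ## sagFraction is defined at the protocol level: the fractional relaxation
  ## (Vss - Vpeak)/(Vbase - Vpeak) a noise-free step of this duration shows.
  ## Solve for the internal slow-relaxation amplitude producing it (the fast
  ## RC charge and the slow sag overlap, so the internal amplitude is larger
  ## than the measured ratio).
  sagAmp <- 0
  if (mode == "cc" && params@sagFraction > 0)
    sagAmp <- .sagInternalAmplitude(params@sagFraction, tauS, sagTau,
                                    protocol$duration[1], dt)

  mat <- matrix(0, n, nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    amp <- protocol$amplitude[i]
    on <- protocol$onset[i]
    off <- on + protocol$duration[i]
    if (mode == "cc") {
      v <- rep(params@restingPotential, n)
      defl <- amp * rin * 1e-3       # pA * MOhm = uV -> mV via 1e-3
      inStep <- t >= on & t < off
      s <- t[inStep] - on
      v[inStep] <- v[inStep] + defl * ((1 - exp(-s / tauS)) -
        sagAmp * (1 - exp(-s / sagTau)))
      post <- t >= off
      if (any(post) && any(inStep)) {
        vEnd <- v[max(which(inStep))]
        u <- t[post] - off
        v[post] <- params@restingPotential +
          (vEnd - params@restingPotential) * exp(-u / tauS)
      }
      if (params@noiseSd > 0) v <- v + rnorm(n, 0, params@noiseSd)
      mat[, i] <- v
    } else {
      ## membrane voltage state (relative to holding), piecewise exact
      tauVc <- cm * (rs * rin / (rs + rin)) * 1e-6
      vm <- numeric(n)
      cmd <- ifelse(t >= on & t < off, amp, 0)
      segStart <- c(0, on, off)
      vm0 <- 0
      for (k in seq_along(segStart)) {
        a <- segStart[k]
        b <- if (k < length(segStart)) segStart[k + 1] else sweepDuration
        idx <- which(t >= a & t < b)
        if (!length(idx)) next
        cmdSeg <- if (k == 2) amp else 0
        vinf <- cmdSeg * rin / (rs + rin)
        s <- t[idx] - a
        vm[idx] <- vinf + (vm0 - vinf) * exp(-s / tauVc)
        vm0 <- vinf + (vm0 - vinf) * exp(-(b - a) / tauVc)
      }
      cur <- (cmd - vm) / rs * 1000   # mV / MOhm = nA -> pA
      if (params@noiseSd > 0) cur <- cur + rnorm(n, 0, params@noiseSd)
      mat[, i] <- cur
    }
  }

  SweepSet(mat, dt = dt,
           signalKind = if (mode == "cc") "cc_voltage" else "vc_current",
           protocol = protocol,
           ljpApplied = if (mode == "cc") 15 else 0,
           cellId = cellId, groupLabel = groupLabel,
           meta = list(truth = list(
             restingPotential = params@restingPotential,
             inputResistance = rin, capacitance = cm,
             seriesResistance = rs, sagFraction = params@sagFraction,
             tauMs = rin * cm * 1e-3, sagTau = sagTau)))
}

#' Generate stylised spiking sweeps with true spike times
#'
#' Sub-threshold dynamics follow the RC membrane of `membrane`, capped 5 mV
#' below the spike threshold. For step currents at or above `rheobaseTrue`
#' the sweep carries `max(1, round(gainTrue * (I - rheobaseTrue) * duration))`
#' spikes (capped by the refractory period), placed evenly through the step.
#' Each spike is a stylised template: a 2-ms sub-threshold ramp rising at
#' < 10 mV/ms into the threshold point, a fast linear upstroke to `apPeak`
#' (far above 10 mV/ms, so the phase-plot rule fires exactly at
#' `thresholdTrue`), a repolarisation to the fAHP minimum
#' (`thresholdTrue - fahpDepth`), and an exponential recovery.
#'
#' @param params a [SpikingParams-class] object (ground truth).
#' @param protocol data.frame with columns amplitude (pA), onset (s),
#'   duration (s).
#' @param membrane a [MembraneParams-class] for the passive backbone.
#' @param dt sampling interval, s.
#' @param sweepDuration sweep length, s.
#' @param noiseSd additive Gaussian voltage noise, mV.
#' @param seed optional integer seed.
#' @param cellId,groupLabel metadata.
#' @return a [SweepSet-class]; `groundTruth()` holds the parameters and
#'   `meta$spikeTimes` the per-sweep true threshold-crossing times (s).
#' @export
genSpikingTraces <- function(params, protocol, membrane = membraneParams(),
                             dt = 5e-5, sweepDuration = NULL, noiseSd = 0,
                             seed = NULL, cellId = "cell", groupLabel = "NA") {
  stopifnot(is(params, "SpikingParams"))
  validObject(params)
  .checkProtocol(protocol, dt)
  if (any(protocol$duration < params@refractory))
    stop("invalid protocol: step shorter than the refractory period")
  if (!is.null(seed)) set.seed(seed)

  thr <- params@thresholdTrue
  vCap <- thr - 5
  fahpMin <- thr - params@fahpDepth
  rampDur <- 2e-3
  upDur <- 4e-4
  downDur <- 5e-4
  recTau <- 5e-3

  if (is.null(sweepDuration))
    sweepDuration <- max(protocol$onset + 1.2 * protocol$duration)
  n <- round(sweepDuration / dt)
  t <- timeAxis(n, dt)
  rin <- membrane@inputResistance
  tauS <- rin * membrane@capacitance * 1e-6
  vrest <- membrane@restingPotential

  mat <- matrix(0, n, nrow(protocol))
  spikeTimes <- vector("list", nrow(protocol))
  for (i in seq_len(nrow(protocol))) {
    amp <- protocol$amplitude[i]
    on <- protocol$onset[i]
    dur <- protocol$duration[i]
    off <- on + dur
    ## capped passive backbone
    v <- rep(vrest, n)
    defl <- amp * rin * 1e-3
    inStep <- t >= on & t < off
    s <- t[inStep] - on
    v[inStep] <- vrest + defl * (1 - exp(-s / tauS))
    post <- t >= off
    if (any(post) && any(inStep)) {
      u <- t[post] - off
      v[post] <- vrest + (v[max(which(inStep))] - vrest) * exp(-u / tauS)
    }
    v <- pmin(v, vCap)
    base <- v

    nSpk <- 0L
    if (amp >= params@rheobaseTrue) {
      nSpk <- max(1, round(params@gainTrue * (amp - params@rheobaseTrue) * dur))
      nSpk <- min(nSpk, floor(dur / params@refractory))
    }
    st <- numeric(0)
    if (nSpk > 0) {
      st <- on + (seq_len(nSpk) - 0.5) * dur / nSpk
      prevEnd <- -Inf
      for (tk in st) {
        iThr <- round(tk / dt) + 1L
        iRamp <- max(round(max(tk - rampDur, prevEnd) / dt) + 1L, 1L)
        iPeak <- round((tk + upDur) / dt) + 1L
        iDown <- round((tk + upDur + downDur) / dt) + 1L
        iRecEnd <- min(round((tk + dur / nSpk - rampDur) / dt) + 1L, n)
        if (iThr > n) break
        if (iRamp < iThr)
          v[iRamp:iThr] <- seq(v[iRamp], thr, length.out = iThr - iRamp + 1L)
        v[iThr] <- thr
        iPeak <- min(iPeak, n); iDown <- min(iDown, n)
        if (iPeak > iThr)
          v[iThr:iPeak] <- seq(thr, params@apPeak,
                               length.out = iPeak - iThr + 1L)
        if (iDown > iPeak)
          v[iPeak:iDown] <- seq(params@apPeak, fahpMin,
                                length.out = iDown - iPeak + 1L)
        if (iRecEnd > iDown) {
          j <- (iDown + 1L):iRecEnd
          v[j] <- base[j] + (fahpMin - base[j]) *
            exp(-(t[j] - t[iDown]) / recTau)
        }
        prevEnd <- t[min(iRecEnd, n)]
      }
      st <- st[st <= t[n]]
    }
    if (noiseSd > 0) v <- v + rnorm(n, 0, noiseSd)
    mat[, i] <- v
    spikeTimes[[i]] <- st
  }

  SweepSet(mat, dt = dt, signalKind = "cc_voltage", protocol = protocol,
           ljpApplied = 15, cellId = cellId, groupLabel = groupLabel,
           meta = list(truth = list(
             rheobaseTrue = params@rheobaseTrue, gainTrue = params@gainTrue,
             thresholdTrue = thr, apPeak = params@apPeak,
             refractory = params@refractory, fahpDepth = params@fahpDepth),
             spikeTimes = spikeTimes))
}

## invert measured-sag -> internal relaxation amplitude on the noise-free
## closed form (monotone in the amplitude; bisection via uniroot)
.sagInternalAmplitude <- function(target, tauS, sagTau, duration, dt) {
  s <- seq(0, duration, by = dt)
  fast <- 1 - exp(-s / tauS)
  slow <- 1 - exp(-s / sagTau)
  ## same conventions as the estimator: steady state is the mean over the
  ## last 10% of the step
  ssIdx <- s >= 0.9 * duration
  measured <- function(a) {
    f <- fast - a * slow
    fPeak <- max(f)
    (fPeak - mean(f[ssIdx])) / fPeak - target
  }
  stats::uniroot(measured, c(0, 0.995), tol = 1e-10)$root
}

.checkProtocol <- function(protocol, dt) {
  if (!is.data.frame(protocol) ||
      !all(c("amplitude", "onset", "duration") %in% names(protocol)) ||
      nrow(protocol) < 1L)
    stop("invalid protocol: need a data.frame with amplitude, onset, duration")
  if (!is.finite(dt) || dt <= 0)
    stop("invalid protocol: dt must be positive")
  if (any(!is.finite(protocol$duration)) || any(protocol$duration <= 0))
    stop("invalid protocol: step durations must be positive")
  if (any(protocol$onset < 0))
    stop("invalid protocol: step onsets must be non-negative")
  invisible(TRUE)
}

#' Step-current protocol helper
#'
#' @param amplitudes step amplitudes (pA or mV).
#' @param onset common onset, s.
#' @param duration common duration, s.
#' @return protocol data.frame for the generators.
#' @export
stepProtocol <- function(amplitudes, onset = 0.1, duration = 0.5) {
  data.frame(amplitude = amplitudes, onset = onset, duration = duration)
}
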