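## Passive membrane properties from step protocols.
##
## Window conventions (the acquisition papers rarely state them): baseline is
## the 50 ms preceding step onset (or all pre-onset samples when shorter);
## "steady state" is the last 10% of the step. Both are configurable.

.preStepBaseline <- function(v, t, onset, baselineMs = 50) {
  idx <- which(t < onset & t >= onset - baselineMs * 1e-3)
  if (!length(idx)) idx <- which(t < onset)
  if (!length(idx)) stop("no pre-stimulus samples for the baseline")
  mean(v[idx])
}

.steadyState <- function(v, t, onset, duration, fraction = 0.1) {
  idx <- which(t >= onset + (1 - fraction) * duration & t < onset + duration)
  if (!length(idx)) stop("steady-state window is empty")
  mean(v[idx])
}

#' Series resistance with quality control
#'
#' Rs is computed per sweep from the initial peak of the capacitive transient
#' elicited by small voltage steps: `Rs = dV / I_peak`. The cell fails QC if
#' the mean Rs exceeds `rsMax` (30 M-ohm) or the relative variation across
#' the experiment, `(max - min)/min`, exceeds `maxVariation` (30%).
#'
#' @param sweeps a voltage-clamp [SweepSet-class] of small steps (1 mV in the
#'   reference protocol).
#' @param rsMax QC ceiling on Rs, M-ohm.
#' @param maxVariation QC ceiling on the relative Rs variation.
#' @param transientMs window after onset searched for the peak transient, ms.
#' @return list with `rs` (per-sweep, M-ohm), `rsMean`, `variation`, `qcPass`.
#' @export
seriesResistanceQc <- function(sweeps, rsMax = 30, maxVariation = 0.3,
                               transientMs = 10) {
  stopifnot(is(sweeps, "SweepSet"))
  if (sweeps@signalKind != "vc_current")
    stop("series resistance needs voltage-clamp sweeps")
  t <- timeAxis(nrow(sweeps@samples), sweeps@dt)
  rs <- vapply(seq_len(nSweeps(sweeps)), function(i) {
    p <- sweeps@protocol[i, ]
    v <- sweeps@samples[, i]
    base <- .preStepBaseline(v, t, p$onset)
    win <- which(t >= p$onset & t < p$onset + transientMs * 1e-3)
    dev <- v[win] - base
    peak <- dev[which.max(abs(dev))]
    iss <- .steadyState(v, t, p$onset, p$duration) - base
    if (abs(peak) < 1e-9 || abs(peak) <= 1.05 * abs(iss))
      stop("no detectable capacitive transient in sweep ", i)
    1000 * abs(p$amplitude) / abs(peak)   # mV/pA -> GOhm; *1000 -> MOhm
  }, numeric(1))
  variation <- if (length(rs) > 1) (max(rs) - min(rs)) / min(rs) else 0
  list(rs = rs, rsMean = mean(rs), variation = variation,
       qcPass = mean(rs) <= rsMax && variation <= maxVariation)
}

#' Slope of a charge-voltage relation
#'
#' Least-squares slope of Q (fC) against V (mV); the slope is the membrane
#' capacitance in pF.
#'
#' @param v step amplitudes, mV (magnitudes).
#' @param q transient charges, fC (magnitudes).
#' @return slope, pF.
#' @export
chargeVoltageSlope <- function(v, q) {
  if (length(unique(v)) < 2L)
    stop("capacitance fit is singular: need at least two distinct step amplitudes")
  unname(coef(lm(q ~ v))[2])
}

#' Membrane capacitance from the charge-voltage plot
#'
#' Integrates the transient capacitive current (relative to the step's steady
#' state) for each voltage step to obtain the charge Q, then reports the
#' least-squares slope of Q against V (`Cm = Q/V`). With a non-negligible
#' series resistance the raw charge underestimates Cm by `(Rm/(Rs+Rm))^2`;
#' `correctRs = TRUE` (default) estimates Rs and Rm from the same sweeps and
#' rescales each Q accordingly.
#'
#' @param sweeps a voltage-clamp [SweepSet-class] with at least two distinct
#'   step amplitudes.
#' @param correctRs apply the series-resistance correction.
#' @param transientMs integration window after onset, ms.
#' @return list with `cm` (pF), `q` (fC per sweep), `v` (mV per sweep).
#' @export
membraneCapacitance <- function(sweeps, correctRs = TRUE, transientMs = 25) {
  stopifnot(is(sweeps, "SweepSet"))
  if (sweeps@signalKind != "vc_current")
    stop("capacitance needs voltage-clamp sweeps")
  t <- timeAxis(nrow(sweeps@samples), sweeps@dt)
  dt <- sweeps@dt
  qs <- vs <- numeric(nSweeps(sweeps))
  for (i in seq_len(nSweeps(sweeps))) {
    p <- sweeps@protocol[i, ]
    v <- sweeps@samples[, i]
    base <- .preStepBaseline(v, t, p$onset)
    iss <- .steadyState(v, t, p$onset, p$duration)
    win <- which(t >= p$onset &
                 t < p$onset + min(transientMs * 1e-3, p$duration))
    dev <- v[win] - iss
    ## trapezoidal integral of the transient, pA*s -> fC via *1e3
    q <- sum((dev[-1] + dev[-length(dev)]) / 2) * dt * 1e3
    if (correctRs) {
      peak <- dev[which.max(abs(dev))] + iss - base
      rsEst <- 1000 * abs(p$amplitude) / abs(peak)
      rmEst <- 1000 * abs(p$amplitude) / abs(iss - base) - rsEst
      if (is.finite(rmEst) && rmEst > 0)
        q <- q * ((rsEst + rmEst) / rmEst)^2
    }
    qs[i] <- abs(q)
    vs[i] <- abs(p$amplitude)
  }
  list(cm = chargeVoltageSlope(vs, qs), q = qs, v = vs)
}

#' Input resistance from hyperpolarizing steps
#'
#' Slope of the steady-state voltage (end of the step) against injected
#' current, over hyperpolarizing sweeps (-60 to -20 pA in the reference
#' protocol).
#'
#' @param sweeps a current-clamp [SweepSet-class]; all step amplitudes must
#'   be negative and at least two distinct levels are required.
#' @param steadyFraction final fraction of the step averaged as steady state.
#' @return input resistance, M-ohm.
#' @export
inputResistance <- function(sweeps, steadyFraction = 0.1) {
  stopifnot(is(sweeps, "SweepSet"))
  if (sweeps@signalKind != "cc_voltage")
    stop("input resistance needs current-clamp sweeps")
  amps <- sweeps@protocol$amplitude
  if (any(amps >= 0))
    stop("input resistance requires hyperpolarizing (negative) steps")
  if (length(unique(amps)) < 2L)
    stop("need at least two distinct current levels")
  t <- timeAxis(nrow(sweeps@samples), sweeps@dt)
  vss <- vapply(seq_len(nSweeps(sweeps)), function(i) {
    p <- sweeps@protocol[i, ]
    .steadyState(sweeps@samples[, i], t, p$onset, p$duration, steadyFraction)
  }, numeric(1))
  unname(coef(lm(vss ~ amps))[2]) * 1000   # mV/pA -> MOhm
}

#' Membrane time constant from small hyperpolarizing pulses
#'
#' Averages the sweeps (ten -20 pA, 100 ms pulses in the reference protocol),
#' then fits a single exponential to the onset response. The fit window runs
#' from 5% of the step duration past onset (skipping any pipette transient)
#' to three times a crude initial tau estimate (time to 63.2% of the
#' deflection).
#'
#' @param sweeps a current-clamp [SweepSet-class] of identical pulses.
#' @param skipFraction fraction of the step duration skipped after onset.
#' @return time constant, ms.
#' @export
membraneTimeConstant <- function(sweeps, skipFraction = 0.05) {
  stopifnot(is(sweeps, "SweepSet"))
  if (sweeps@signalKind != "cc_voltage")
    stop("time constant needs current-clamp sweeps")
  p <- sweeps@protocol[1, ]
  v <- rowMeans(sweeps@samples)
  t <- timeAxis(length(v), sweeps@dt)
  base <- .preStepBaseline(v, t, p$onset)
  vss <- .steadyState(v, t, p$onset, p$duration)
  defl <- vss - base
  if (abs(defl) < 0.2)
    stop("fit error: no measurable voltage deflection (", signif(defl, 3),
         " mV)")
  ## crude tau: first crossing of 63.2% of the deflection
  inStep <- which(t >= p$onset & t < p$onset + p$duration)
  crossed <- inStep[abs(v[inStep] - base) >= 0.632 * abs(defl)]
  if (!length(crossed)) stop("fit error: voltage never reaches 63% of deflection")
  tau0 <- t[crossed[1]] - p$onset
  w0 <- p$onset + skipFraction * p$duration
  w1 <- min(p$onset + 5 * tau0, p$onset + p$duration)
  idx <- which(t >= w0 & t < w1)
  if (length(idx) < 5L) stop("fit error: fit window too short")
  ## the asymptote is pinned to the measured steady state: with it free, the
  ## short fit window leaves tau and the asymptote poorly separated
  df <- data.frame(tt = t[idx] - t[idx[1]], vv = v[idx] - vss)
  fit <- tryCatch(
    minpack.lm::nlsLM(vv ~ b * exp(-tt / tau), data = df,
                      start = list(b = v[idx[1]] - vss, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit error: exponential fit failed (", conditionMessage(e), ")"))
  tau <- unname(coef(fit)["tau"]) * 1000
  if (!is.finite(tau) || tau <= 0) stop("fit error: non-positive tau")
  tau
}

#' Sag during hyperpolarizing steps
#'
#' Default estimator (`method = "deflection"`):
#' `sag% = 100 * (Vss - Vpeak) / (Vbaseline - Vpeak)`, the percentage of the
#' peak deflection that relaxes back by the end of the step. The literal
#' peak-over-steady-state ratio `(Vpeak - Vbase)/(Vss - Vbase)` (a number
#' near 1) is available as `method = "ratio"`. The peak is located on a 1-ms
#' running mean so single noise samples do not masquerade as sag.
#'
#' @param sweeps a current-clamp [SweepSet-class] of hyperpolarizing steps
#'   (-120 to -510 pA in the reference protocol).
#' @param method "deflection" (sag percentage) or "ratio".
#' @param steadyFraction final fraction of the step averaged as steady state.
#' @return list with `perStep` values and their `summary` (mean).
#' @export
sagRatio <- function(sweeps, method = c("deflection", "ratio"),
                     steadyFraction = 0.1) {
  method <- match.arg(method)
  stopifnot(is(sweeps, "SweepSet"))
  if (sweeps@signalKind != "cc_voltage")
    stop("sag needs current-clamp sweeps")
  t <- timeAxis(nrow(sweeps@samples), sweeps@dt)
  k <- max(1L, round(1e-3 / sweeps@dt))
  kern <- rep(1 / k, k)
  perStep <- vapply(seq_len(nSweeps(sweeps)), function(i) {
    p <- sweeps@protocol[i, ]
    v <- sweeps@samples[, i]
    base <- .preStepBaseline(v, t, p$onset)
    vSm <- as.numeric(stats::filter(v, kern, sides = 2))
    inStep <- which(t >= p$onset & t < p$onset + p$duration & !is.na(vSm))
    vPeak <- min(vSm[inStep])
    if (vPeak >= base)
      stop("no hyperpolarizing deflection in sweep ", i)
    vss <- .steadyState(v, t, p$onset, p$duration, steadyFraction)
    if (method == "deflection") 100 * (vss - vPeak) / (base - vPeak)
    else (vPeak - base) / (vss - base)
  }, numeric(1))
  list(perStep = perStep, summary = mean(perStep))
}
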