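## Parameter bundles for the synthetic generators (ground truth carriers).

#' Ground-truth passive membrane parameters
#'
#' @slot restingPotential mV (already LJP-corrected; the generators emit
#'   corrected voltages by default).
#' @slot inputResistance M-ohm, > 0.
#' @slot capacitance pF, > 0. The membrane time constant implied by the model
#'   is `inputResistance * capacitance` (12 ms for 150 M-ohm and 80 pF).
#' @slot seriesResistance M-ohm (voltage-clamp access resistance).
#' @slot sagFraction dimensionless in [0, 1): fractional slow relaxation of
#'   the step deflection back toward baseline (h-current-like sag).
#' @slot noiseSd additive Gaussian noise SD: mV in current clamp, pA in
#'   voltage clamp.
#' @export
setClass("MembraneParams",
  representation(restingPotential = "numeric", inputResistance = "numeric",
                 capacitance = "numeric", seriesResistance = "numeric",
                 sagFraction = "numeric", noiseSd = "numeric"))

setValidity("MembraneParams", function(object) {
  msg <- character()
  if (object@inputResistance <= 0) msg <- c(msg, "inputResistance must be > 0")
  if (object@capacitance <= 0) msg <- c(msg, "capacitance must be > 0")
  if (object@seriesResistance < 0) msg <- c(msg, "seriesResistance must be >= 0")
  if (object@sagFraction < 0 || object@sagFraction >= 1)
    msg <- c(msg, "sagFraction must lie in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param restingPotential,inputResistance,capacitance,seriesResistance,sagFraction,noiseSd
#'   see the class slots.
#' @return a `MembraneParams` object.
#' @rdname MembraneParams-class
#' @export
membraneParams <- function(restingPotential = -85, inputResistance = 133,
                           capacitance = 90, seriesResistance = 12,
                           sagFraction = 0, noiseSd = 0) {
  new("MembraneParams", restingPotential = restingPotential,
      inputResistance = inputResistance, capacitance = capacitance,
      seriesResistance = seriesResistance, sagFraction = sagFraction,
      noiseSd = noiseSd)
}

#' Ground-truth spiking parameters for the stylised spiking generator
#'
#' @slot rheobaseTrue pA, > 0: minimum step current that elicits a spike.
#' @slot gainTrue Hz/pA, > 0: slope of the F-I relation above rheobase.
#' @slot thresholdTrue mV: phase-plot threshold of the stylised action
#'   potential.
#' @slot apPeak mV: spike peak voltage.
#' @slot refractory s: minimum inter-spike interval (caps the spike count).
#' @slot fahpDepth mV, > 0: depth of the fast afterhyperpolarisation below
#'   threshold.
#' @export
setClass("SpikingParams",
  representation(rheobaseTrue = "numeric", gainTrue = "numeric",
                 thresholdTrue = "numeric", apPeak = "numeric",
                 refractory = "numeric", fahpDepth = "numeric"))

setValidity("SpikingParams", function(object) {
  msg <- character()
  if (object@rheobaseTrue <= 0) msg <- c(msg, "rheobaseTrue must be > 0")
  if (object@gainTrue <= 0) msg <- c(msg, "gainTrue must be > 0")
  if (object@refractory <= 0) msg <- c(msg, "refractory must be > 0")
  if (object@apPeak <= object@thresholdTrue)
    msg <- c(msg, "apPeak must exceed thresholdTrue")
  if (object@fahpDepth <= 0) msg <- c(msg, "fahpDepth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param rheobaseTrue,gainTrue,thresholdTrue,apPeak,refractory,fahpDepth see
#'   the class slots.
#' @return a `SpikingParams` object.
#' @rdname SpikingParams-class
#' @export
spikingParams <- function(rheobaseTrue = 120, gainTrue = 0.1,
                          thresholdTrue = -56, apPeak = 45,
                          refractory = 2e-3, fahpDepth = 20) {
  new("SpikingParams", rheobaseTrue = rheobaseTrue, gainTrue = gainTrue,
      thresholdTrue = thresholdTrue, apPeak = apPeak, refractory = refractory,
      fahpDepth = fahpDepth)
}

#' Specification of a synthetic spontaneous-PSC recording
#'
#' @slot rate Hz: Poisson event rate.
#' @slot amplitudeDist named amplitude distribution (pA, positive magnitude):
#'   `list(name = "lognormal", meanlog =, sdlog =)`,
#'   `list(name = "normal", mean =, sd =)` (truncated at 1 pA),
#'   `list(name = "uniform", min =, max =)`, or
#'   `list(name = "constant", value =)`.
#' @slot riseTau,decayTau ms: kinetics of the biexponential kernel
#'   (`decayTau > riseTau > 0`).
#' @slot polarity "inward" (events deflect negative) or "outward".
#' @slot duration s: recording length.
#' @slot baselineNoiseSd pA: Gaussian baseline noise SD.
#' @slot baselineMean pA: holding-current baseline.
#' @export
setClass("EventGenSpec",
  representation(rate = "numeric", amplitudeDist = "list",
                 riseTau = "numeric", decayTau = "numeric",
                 polarity = "character", duration = "numeric",
                 baselineNoiseSd = "numeric", baselineMean = "numeric"))

setValidity("EventGenSpec", function(object) {
  msg <- character()
  if (object@rate < 0) msg <- c(msg, "rate must be >= 0")
  if (!(object@decayTau > object@riseTau && object@riseTau > 0))
    msg <- c(msg, "must have decayTau > riseTau > 0")
  if (!object@polarity %in% c("inward", "outward"))
    msg <- c(msg, "polarity must be 'inward' or 'outward'")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@baselineNoiseSd < 0) msg <- c(msg, "baselineNoiseSd must be >= 0")
  if (is.null(object@amplitudeDist$name) ||
      !object@amplitudeDist$name %in%
        c("lognormal", "normal", "uniform", "constant"))
    msg <- c(msg, "amplitudeDist$name must be one of lognormal, normal, uniform, constant")
  if (length(msg)) msg else TRUE
})

#' @param rate,amplitudeDist,riseTau,decayTau,polarity,duration,baselineNoiseSd,baselineMean
#'   see the class slots. The default amplitude distribution is log-normal
#'   with median 10 pA (heavy right tail, as PSC amplitude histograms show).
#' @return an `EventGenSpec` object.
#' @rdname EventGenSpec-class
#' @export
eventGenSpec <- function(rate = 4,
                         amplitudeDist = list(name = "lognormal",
                                              meanlog = log(10), sdlog = 0.35),
                         riseTau = 0.5, decayTau = 4,
                         polarity = "inward", duration = 60,
                         baselineNoiseSd = 2, baselineMean = -20) {
  new("EventGenSpec", rate = rate, amplitudeDist = amplitudeDist,
      riseTau = riseTau, decayTau = decayTau, polarity = polarity,
      duration = duration, baselineNoiseSd = baselineNoiseSd,
      baselineMean = baselineMean)
}

#' Specification of a synthetic go/no-go session
#'
#' @slot nBlocks number of blocks (10 in the study design).
#' @slot trialsPerBlock trials per block, even (equal CS+/CS- counts; 20 in
#'   the study design).
#' @slot pLickCsPlus,pLickCsMinus per-block lick probabilities (recycled to
#'   `nBlocks`), in [0, 1].
#' @slot lickIntervals number of 0.5-s response intervals per trial (4 in the
#'   study design).
#' @slot gradedLicks if TRUE each interval is an independent Bernoulli draw;
#'   if FALSE (default) a trial is an all-intervals lick response with the
#'   block probability, otherwise lick-free.
#' @slot pInvalid probability that a trial is invalid (animal left the port).
#' @export
setClass("SessionSpec",
  representation(nBlocks = "integer", trialsPerBlock = "integer",
                 pLickCsPlus = "numeric", pLickCsMinus = "numeric",
                 lickIntervals = "integer", gradedLicks = "logical",
                 pInvalid = "numeric"))

setValidity("SessionSpec", function(object) {
  msg <- character()
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
  if (object@trialsPerBlock < 2L || object@trialsPerBlock %% 2L != 0L)
    msg <- c(msg, "trialsPerBlock must be even (equal CS+/CS- counts)")
  if (any(object@pLickCsPlus < 0 | object@pLickCsPlus > 1) ||
      any(object@pLickCsMinus < 0 | object@pLickCsMinus > 1))
    msg <- c(msg, "lick probabilities must lie in [0, 1]")
  if (object@lickIntervals < 1L) msg <- c(msg, "lickIntervals must be >= 1")
  if (object@pInvalid < 0 || object@pInvalid >= 1)
    msg <- c(msg, "pInvalid must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param nBlocks,trialsPerBlock,pLickCsPlus,pLickCsMinus,lickIntervals,gradedLicks,pInvalid
#'   see the class slots. Defaults follow the study design: 10 blocks of 20
#'   trials (200 trials), 4 half-second response intervals.
#' @return a `SessionSpec` object.
#' @rdname SessionSpec-class
#' @export
sessionSpec <- function(nBlocks = 10, trialsPerBlock = 20,
                        pLickCsPlus = 0.5, pLickCsMinus = 0.5,
                        lickIntervals = 4, gradedLicks = FALSE,
                        pInvalid = 0) {
  new("SessionSpec", nBlocks = as.integer(nBlocks),
      trialsPerBlock = as.integer(trialsPerBlock),
      pLickCsPlus = rep_len(pLickCsPlus, nBlocks),
      pLickCsMinus = rep_len(pLickCsMinus, nBlocks),
      lickIntervals = as.integer(lickIntervals),
      gradedLicks = gradedLicks, pInvalid = pInvalid)
}
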