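## Shared fixture builders (everything is generated in code at test time).

## voltage-clamp cell for Rs/Cm protocols
vcCell <- function(cm = 50, rin = 150, rs = 10, noise = 0, seed = NULL) {
  genPassiveStepTraces(
    membraneParams(inputResistance = rin, capacitance = cm,
                   seriesResistance = rs, noiseSd = noise),
    stepProtocol(-(1:5), onset = 0.02, duration = 0.1),
    mode = "vc", seed = seed)
}

## current-clamp input-resistance protocol (-60..-20 pA, 500 ms)
rinCell <- function(rin = 133, cm = 90, noise = 0, seed = NULL, sag = 0) {
  genPassiveStepTraces(
    membraneParams(inputResistance = rin, capacitance = cm,
                   sagFraction = sag, noiseSd = noise),
    stepProtocol(seq(-60, -20, 10), onset = 0.1, duration = 0.5),
    seed = seed)
}

## ten -20 pA / 100 ms pulses for the time constant
tauCell <- function(rin = 133, cm = 90.2255639, noise = 0, seed = NULL) {
  genPassiveStepTraces(
    membraneParams(inputResistance = rin, capacitance = cm, noiseSd = noise),
    stepProtocol(rep(-20, 10), onset = 0.05, duration = 0.1),
    seed = seed)
}

## build a current-clamp SweepSet with an exact number of brief spikes per
## sweep (independent of the spiking generator)
countedSpikeSweeps <- function(counts, amps, dt = 5e-5, onset = 0.1,
                               duration = 0.5) {
  n <- round((onset + duration + 0.05) / dt)
  mat <- vapply(seq_along(counts), function(i) {
    v <- rep(-70, n)
    k <- counts[i]
    if (k > 0) {
      at <- onset + (seq_len(k) - 0.5) * duration / k
      v[round(at / dt) + 1L] <- 20
    }
    v
  }, numeric(n))
  SweepSet(mat, dt = dt, signalKind = "cc_voltage",
           protocol = stepProtocol(amps, onset, duration))
}

## a trace carrying hand-placed biexponential events on a known baseline
eventTrace <- function(onsets, amps, riseTau = 0.5, decayTau = 4,
                       duration = 2, noise = 0, baseline = -20, dt = 5e-5,
                       seed = 1) {
  set.seed(seed)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  v <- rep(baseline, n) + if (noise > 0) rnorm(n, 0, noise) else 0
  for (i in seq_along(onsets))
    v <- v - amps[i] * pscKernel((t - onsets[i]) * 1000, riseTau, decayTau)
  Trace(v, dt = dt, signalKind = "vc_current")
}

## deterministic "noisy" baseline with known SD: alternating +/- sd
alternatingNoise <- function(n, sd) sd * rep_len(c(1, -1), n)

## session whose block percent-correct values are exactly as requested
sessionWithBlockAccuracy <- function(pctCorrect, trialsPerBlock = 20) {
  half <- trialsPerBlock / 2
  rows <- lapply(seq_along(pctCorrect), function(b) {
    nWrong <- round((1 - pctCorrect[b] / 100) * trialsPerBlock)
    lab <- rep(c("CS+", "CS-"), each = half)
    ## correct: CS+ licks all, CS- licks none; flip the first nWrong trials
    licks <- lapply(seq_len(trialsPerBlock), function(j) {
      correct <- j > nWrong
      lickOn <- (lab[j] == "CS+") == correct
      rep(as.integer(lickOn), 4)
    })
    df <- data.frame(block = b, csLabel = lab, valid = TRUE)
    df$intervalLicks <- licks
    df
  })
  trials <- do.call(rbind, rows)
  trials$trial <- seq_len(nrow(trials))
  Session(trials[, c("trial", "block", "csLabel", "valid", "intervalLicks")])
}

## brute-force pairwise AUC oracle (normalised Mann-Whitney U with ties)
aucOracle <- function(scoresPos, scoresNeg) {
  s <- outer(scoresPos, scoresNeg, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(s)
}

## brute-force two-sample KS oracle: evaluate both ECDFs at every pooled point
ksOracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}
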