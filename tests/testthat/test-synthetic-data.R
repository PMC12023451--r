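## Generators: closed-form correctness, ground-truth contracts, determinism.

test_that("passive generator follows the RC step response", {
  ## Ohm's law: -20 pA into 100 MOhm -> -2 mV steady-state deflection
  ss <- genPassiveStepTraces(
    membraneParams(restingPotential = -85, inputResistance = 100,
                   capacitance = 100),
    stepProtocol(-20, onset = 0.1, duration = 0.5))
  v <- sweepMatrix(ss)[, 1]
  t <- (seq_along(v) - 1) * samplingInterval(ss)
  vss <- mean(v[t > 0.55 & t < 0.6])
  expect_equal(vss - (-85), -2, tolerance = 1e-6)

  ## tau = Rin * Cm: 150 MOhm x 80 pF -> 63.2% of the deflection at 12 ms
  ss2 <- genPassiveStepTraces(
    membraneParams(inputResistance = 150, capacitance = 80),
    stepProtocol(-20, onset = 0.1, duration = 0.5))
  v2 <- sweepMatrix(ss2)[, 1]
  i12 <- round(0.112 / samplingInterval(ss2)) + 1L
  frac <- (v2[i12] - (-85)) / (-20 * 150 * 1e-3)
  expect_equal(frac, 1 - exp(-1), tolerance = 1e-3)

  ## noise-free trace matches the closed form everywhere (<= 0.1% of defl)
  mp <- membraneParams(inputResistance = 120, capacitance = 70)
  ss3 <- genPassiveStepTraces(mp, stepProtocol(-40, 0.05, 0.3))
  v3 <- sweepMatrix(ss3)[, 1]
  t3 <- (seq_along(v3) - 1) * samplingInterval(ss3)
  tauS <- 120 * 70 * 1e-6
  inStep <- t3 >= 0.05 & t3 < 0.35
  closed <- -85 + (-40 * 120 * 1e-3) * (1 - exp(-(t3[inStep] - 0.05) / tauS))
  expect_lt(max(abs(v3[inStep] - closed)), 0.001 * abs(-40 * 120 * 1e-3))
})

test_that("sag is generated at the requested measured fraction", {
  ss <- genPassiveStepTraces(
    membraneParams(inputResistance = 133, capacitance = 90,
                   sagFraction = 0.05),
    stepProtocol(-300, onset = 0.1, duration = 0.5))
  v <- sweepMatrix(ss)[, 1]
  t <- (seq_along(v) - 1) * samplingInterval(ss)
  inStep <- t >= 0.1 & t < 0.6
  vPeak <- min(v[inStep])
  vss <- mean(v[t >= 0.55 & t < 0.6])
  expect_equal((vss - vPeak) / (-85 - vPeak), 0.05, tolerance = 0.01)
})

test_that("passive generator rejects invalid protocols", {
  mp <- membraneParams()
  expect_error(genPassiveStepTraces(mp, stepProtocol(-20, 0.1, -1)),
               "invalid protocol")
  expect_error(genPassiveStepTraces(mp, stepProtocol(-20), dt = 0),
               "invalid protocol")
  expect_error(genPassiveStepTraces(mp, data.frame(amplitude = -20)),
               "invalid protocol")
})

test_that("spiking generator honours rheobase, count formula and refractory", {
  sp <- spikingParams(rheobaseTrue = 100, gainTrue = 0.1)
  ## sub-rheobase step: no spikes
  sub <- genSpikingTraces(sp, stepProtocol(95, 0.1, 0.5))
  expect_length(sub@meta$spikeTimes[[1]], 0)
  expect_length(detectSpikes(getSweep(sub, 1)), 0)
  ## at rheobase: at least one spike
  at <- genSpikingTraces(sp, stepProtocol(100, 0.1, 0.5))
  expect_gte(length(at@meta$spikeTimes[[1]]), 1)
  ## count formula: I = 300 pA, 500 ms -> round(0.1 * 200 * 0.5) = 10 spikes
  hi <- genSpikingTraces(sp, stepProtocol(300, 0.1, 0.5))
  expect_length(hi@meta$spikeTimes[[1]], 10)
  expect_length(detectSpikes(getSweep(hi, 1)), 10)
  ## detected times match the true times within 0.5 ms
  st <- detectSpikes(getSweep(hi, 1))
  expect_lt(max(abs(st - hi@meta$spikeTimes[[1]])), 5e-4)
  ## step shorter than the refractory period
  expect_error(genSpikingTraces(sp, stepProtocol(300, 0.1, 1e-3)),
               "refractory")
})

test_that("synaptic trace generator is Poisson, additive and reproducible", {
  ## rate 0: pure noise, empty truth table
  quiet <- genSynapticTrace(eventGenSpec(rate = 0, duration = 5), seed = 11)
  expect_equal(nrow(groundTruth(quiet)), 0)
  expect_equal(sd(traceSamples(quiet)), 2, tolerance = 0.05)

  ## rate 4 Hz x 100 s: count within 3 * sqrt(400) of 400
  busy <- genSynapticTrace(eventGenSpec(rate = 4, duration = 100), seed = 12)
  expect_lt(abs(nrow(groundTruth(busy)) - 400), 3 * sqrt(400))

  ## determinism: same seed, identical samples
  a <- genSynapticTrace(eventGenSpec(duration = 3), seed = 42)
  b <- genSynapticTrace(eventGenSpec(duration = 3), seed = 42)
  expect_identical(traceSamples(a), traceSamples(b))

  ## additivity: trace minus the kernels equals the same-seed noise baseline
  ## exactly (the noise vector is drawn before the events, so a rate-0 run
  ## with the same seed reproduces it)
  spec <- eventGenSpec(rate = 3, duration = 4)
  withEv <- genSynapticTrace(spec, seed = 7)
  noiseOnly <- genSynapticTrace(eventGenSpec(rate = 0, duration = 4),
                                seed = 7)
  truth <- groundTruth(withEv)
  v <- traceSamples(withEv)
  t <- (seq_along(v) - 1) * samplingInterval(withEv)
  for (i in seq_len(nrow(truth)))
    v <- v + truth$amplitude[i] *
      pscKernel((t - truth$onset[i]) * 1000, truth$riseTau[i],
                truth$decayTau[i])
  expect_equal(v, traceSamples(noiseOnly), tolerance = 1e-6)
})

test_that("generated sessions are balanced, reproducible and scoreable", {
  spec <- sessionSpec(nBlocks = 10, trialsPerBlock = 20)
  ses <- genSession(spec, seed = 5)
  tr <- trialTable(ses)
  expect_equal(nrow(tr), 200)
  for (b in 1:10)
    expect_equal(sum(tr$csLabel[tr$block == b] == "CS+"), 10)

  ## deterministic discrimination: p+ = 1, p- = 0 -> 100% correct everywhere
  perfect <- genSession(sessionSpec(pLickCsPlus = 1, pLickCsMinus = 0),
                        seed = 1)
  bp <- blockPerformance(perfect)
  expect_true(all(bp$blocks$percentCorrect == 100))

  ## reproducibility
  s1 <- genSession(spec, seed = 9)
  s2 <- genSession(spec, seed = 9)
  expect_identical(trialTable(s1), trialTable(s2))

  ## odd trials per block is rejected at spec construction
  expect_error(sessionSpec(trialsPerBlock = 15), "even")
})
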