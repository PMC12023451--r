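## Passive and active membrane-property estimators against ground truth.

test_that("series resistance follows Ohm's law and the QC rules", {
  ## generator: 1 mV step into Rs 10 MOhm peaks at 100 pA -> Rs = 10
  vc <- vcCell(rs = 10)
  qc <- seriesResistanceQc(vc)
  expect_equal(qc$rsMean, 10, tolerance = 1e-3)
  expect_true(qc$qcPass)

  ## 20 -> 28 MOhm across the experiment is a 40% rise: QC fails
  lowRs <- vcCell(rs = 20)
  hiRs <- vcCell(rs = 28)
  drift <- SweepSet(cbind(sweepMatrix(lowRs)[, 1:3], sweepMatrix(hiRs)[, 1:2]),
                    dt = samplingInterval(lowRs), signalKind = "vc_current",
                    protocol = protocolTable(lowRs))
  qc2 <- seriesResistanceQc(drift)
  expect_false(qc2$qcPass)
  expect_gt(qc2$variation, 0.3)

  ## mean Rs above 30 MOhm fails even when stable
  qc3 <- seriesResistanceQc(vcCell(rs = 35))
  expect_false(qc3$qcPass)

  ## noisy recovery within 10%
  qc4 <- seriesResistanceQc(vcCell(rs = 12, noise = 2, seed = 8))
  expect_equal(qc4$rsMean, 12, tolerance = 0.1)

  ## a flat trace has no detectable transient
  flat <- SweepSet(matrix(0, 4000, 2), dt = 5e-5, signalKind = "vc_current",
                   protocol = stepProtocol(c(-1, -2), 0.02, 0.1))
  expect_error(seriesResistanceQc(flat), "transient")
})

test_that("capacitance comes from the charge-voltage slope", {
  ## exact slope on stated Q-V pairs: {(1 mV, 50 fC), (2 mV, 100 fC)} -> 50 pF
  expect_equal(chargeVoltageSlope(c(1, 2), c(50, 100)), 50)
  expect_error(chargeVoltageSlope(c(1, 1), c(50, 52)), "singular")

  ## noise-free synthetic cell: Cm 50 pF recovered within numerical tolerance
  vc <- vcCell(cm = 50, rs = 10)
  expect_equal(membraneCapacitance(vc)$cm, 50, tolerance = 0.01)
  ## with measurement noise, within 5%
  vcN <- vcCell(cm = 50, rs = 10, noise = 2, seed = 31)
  expect_equal(membraneCapacitance(vcN)$cm, 50, tolerance = 0.05)
  ## the uncorrected estimate carries the (Rm/(Rs+Rm))^2 access bias
  naive <- membraneCapacitance(vc, correctRs = FALSE)$cm
  expect_equal(naive / 50, (150 / 160)^2, tolerance = 0.02)
})

test_that("input resistance is the steady-state V-I slope", {
  ## exact deflections -I * 150 MOhm -> 150 MOhm
  expect_equal(inputResistance(rinCell(rin = 150)), 150, tolerance = 1e-3)
  ## noisy recovery within 5%
  expect_equal(inputResistance(rinCell(rin = 133, noise = 0.3, seed = 21)),
               133, tolerance = 0.05)
  ## depolarizing steps violate the protocol
  dep <- genPassiveStepTraces(membraneParams(),
                              stepProtocol(seq(20, 60, 10), 0.1, 0.5))
  expect_error(inputResistance(dep), "hyperpolarizing")
  ## a single current level cannot give a slope
  one <- genPassiveStepTraces(membraneParams(), stepProtocol(-20, 0.1, 0.5))
  expect_error(inputResistance(one), "two distinct")
})

test_that("membrane time constant is recovered by the exponential fit", {
  expect_equal(membraneTimeConstant(tauCell()), 12, tolerance = 0.01)
  expect_equal(membraneTimeConstant(tauCell(noise = 0.5, seed = 14)), 12,
               tolerance = 0.1)
  flat <- SweepSet(matrix(-85, 4000, 10), dt = 5e-5,
                   signalKind = "cc_voltage",
                   protocol = stepProtocol(rep(-20, 10), 0.05, 0.1))
  expect_error(membraneTimeConstant(flat), "fit error")
})

test_that("sag percentage matches the generator's ground truth", {
  sagProto <- stepProtocol(seq(-120, -300, -30), 0.1, 0.5)
  mk <- function(sag, noise = 0, seed = NULL)
    genPassiveStepTraces(membraneParams(inputResistance = 133,
                                        capacitance = 90,
                                        sagFraction = sag, noiseSd = noise),
                         sagProto, seed = seed)
  ## no sag: exactly 0 within discretisation
  expect_lt(abs(sagRatio(mk(0))$summary), 0.05)
  ## 5% sag recovered
  expect_equal(sagRatio(mk(0.05))$summary, 5, tolerance = 0.05)
  ## null simulation with noise stays under 1% absolute
  expect_lt(abs(sagRatio(mk(0, noise = 0.3, seed = 3))$summary), 1)
  ## the literal peak/steady ratio mode sits just above 1 for positive sag
  r <- sagRatio(mk(0.05), method = "ratio")$summary
  expect_gt(r, 1)
  expect_lt(r, 1.1)
  ## depolarizing deflection is an error
  dep <- genPassiveStepTraces(membraneParams(), stepProtocol(100, 0.1, 0.5))
  expect_error(sagRatio(dep), "hyperpolarizing")
})

test_that("spike detection applies the crossing and refractory rules", {
  dt <- 5e-5
  ## subthreshold trace: nothing
  expect_length(detectSpikes(rep(-70, 1000), dt = dt), 0)
  ## doublet separated by 0.8 ms collapses to one detection
  v <- rep(-70, 2000)
  v[500] <- 20
  v[516] <- 20          # 16 samples = 0.8 ms later
  expect_length(detectSpikes(v, dt = dt), 1)
  ## 1.2 ms apart: two detections
  v2 <- rep(-70, 2000)
  v2[500] <- 20
  v2[524] <- 20
  expect_length(detectSpikes(v2, dt = dt), 2)
})

test_that("F-I gain is the regression slope over the first linear points", {
  ## frozen oracle: counts {0,0,5,10,15}/500 ms at {25..225} pA are exactly
  ## linear from the 3rd point; lm on the frequencies gives 0.2 Hz/pA
  ss <- countedSpikeSweeps(c(0, 0, 5, 10, 15), seq(25, 225, 50))
  fc <- fiCurve(ss)
  expect_equal(fc$fi$count, c(0, 0, 5, 10, 15))
  expect_equal(fc$fi$frequency, c(0, 0, 10, 20, 30))
  oracle <- unname(coef(lm(c(10, 20, 30) ~ seq(125, 225, 50)))[2])
  expect_equal(fc$gain, oracle)
  expect_equal(fc$gain, 0.2)
  expect_equal(fc$linearRegion, 3:5)

  ## generator recovery: gain 0.1 Hz/pA within 10%
  sp <- spikingParams(rheobaseTrue = 100, gainTrue = 0.1)
  fiss <- genSpikingTraces(sp, stepProtocol(seq(25, 625, 50), 0.1, 0.5))
  expect_equal(fiCurve(fiss)$gain, 0.1, tolerance = 0.1)

  ## all-zero counts: flagged, gain undefined
  none <- countedSpikeSweeps(c(0, 0, 0), seq(25, 125, 50))
  fc0 <- fiCurve(none)
  expect_false(fc0$gainDefined)
  expect_true(is.na(fc0$gain))

  ## monotonicity of counts in current for the monotone generator
  expect_true(all(diff(fiCurve(fiss)$fi$count) >= 0))
})

test_that("rheobase is the smallest spiking step", {
  ## definition: first spiking sweep at 115 pA
  ss <- countedSpikeSweeps(c(0, 0, 0, 1, 2), seq(100, 120, 5))
  expect_equal(rheobase(ss), 115)
  ## generator: rheobase 120 recovered at the 5 pA grid resolution
  sp <- spikingParams(rheobaseTrue = 120)
  fine <- genSpikingTraces(sp, stepProtocol(seq(100, 150, 5), 0.1, 0.5))
  expect_lte(abs(rheobase(fine) - 120), 5)
  ## all sweeps spiking warns; none spiking errors
  expect_warning(rheobase(countedSpikeSweeps(c(1, 2), c(100, 105))),
                 "smallest")
  expect_error(rheobase(countedSpikeSweeps(c(0, 0), c(100, 105))),
               "no sweep")
})

test_that("AP features follow the phase-plot rules", {
  dt <- 5e-5
  ## piecewise-linear spike: 5 mV/ms up to -60 mV, then 50 mV/ms to +40;
  ## threshold must sit at the slope change (-60 mV)
  seg1 <- seq(-75, -60, by = 5 * dt * 1000)       # 5 mV/ms
  seg2 <- seq(-60, 40, by = 50 * dt * 1000)[-1]   # 50 mV/ms
  seg3 <- seq(40, -70, by = -100 * dt * 1000)[-1]
  v <- c(rep(-75, 200), seg1, seg2, seg3, rep(-70, 400))
  tr <- Trace(v, dt = dt, signalKind = "cc_voltage", stimOnset = 0.005)
  ap <- apFeatures(tr, stimOnset = 0.005)
  expect_equal(ap$threshold, -60, tolerance = 0.5)

  ## arithmetic: threshold -55, peak +45 -> amplitude 100, overshoot 45
  sp <- spikingParams(rheobaseTrue = 100, thresholdTrue = -55, apPeak = 45)
  sw <- genSpikingTraces(sp, stepProtocol(105, 0.1, 0.5))
  ap2 <- apFeatures(getSweep(sw, 1))
  expect_equal(ap2$threshold, -55, tolerance = 0.2)
  expect_equal(ap2$amplitude, 100, tolerance = 0.3)
  expect_equal(ap2$overshoot, 45, tolerance = 0.2)
  expect_gt(ap2$halfWidth, 0)
  ## internal consistency: amplitude == overshoot - threshold when peak > 0
  expect_equal(ap2$amplitude, ap2$overshoot - ap2$threshold, tolerance = 1e-9)

  ## generator threshold recovered within 1.5 mV, with and without noise
  sp3 <- spikingParams(rheobaseTrue = 120, thresholdTrue = -56)
  sw3 <- genSpikingTraces(sp3, stepProtocol(125, 0.1, 0.5))
  expect_lt(abs(apFeatures(getSweep(sw3, 1))$threshold - (-56)), 1.5)
  sw3n <- genSpikingTraces(sp3, stepProtocol(125, 0.1, 0.5), noiseSd = 0.3,
                           seed = 6)
  expect_lt(abs(apFeatures(getSweep(sw3n, 1))$threshold - (-56)), 1.5)

  ## fAHP is the post-peak minimum relative to threshold
  expect_equal(ap2$fahp, -20, tolerance = 0.3)

  ## error paths: no spike; dV/dt never above 10 mV/ms
  expect_error(apFeatures(Trace(rep(-70, 1000), dt = dt,
                                signalKind = "cc_voltage")), "no spike")
  slow <- c(rep(-70, 100), seq(-70, 5, by = 5 * dt * 1000),
            seq(5, -70, by = -5 * dt * 1000), rep(-70, 100))
  expect_error(apFeatures(Trace(slow, dt = dt, signalKind = "cc_voltage")),
               "dV/dt")
})

test_that("central-difference dV/dt agrees with a forward-difference oracle", {
  set.seed(9)
  v <- cumsum(rnorm(500))
  dt <- 5e-5
  n <- length(v)
  central <- (v[3:n] - v[1:(n - 2)]) / (2 * dt * 1000)
  forward <- (v[2:n] - v[1:(n - 1)]) / (dt * 1000)
  ## central difference is the mean of adjacent forward differences
  expect_equal(central, (forward[-1] + forward[-length(forward)]) / 2,
               tolerance = 1e-12)
})
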