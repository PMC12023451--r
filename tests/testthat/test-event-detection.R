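## PSC detection: smoothing kernel, amplitude/kinetics rules, train stats.

test_that("binomial smoothing kernel has the stated exact properties", {
  k <- binomialKernel(25)
  expect_equal(sum(k), 1)
  expect_equal(k, rev(k))                        # symmetric
  expect_equal(k, choose(24, 0:24) / 2^24)
  ## constant trace is unchanged
  expect_equal(binomialSmooth(rep(3.2, 100)), rep(3.2, 100))
  ## unit impulse returns the kernel row
  x <- numeric(101); x[51] <- 1
  expect_equal(binomialSmooth(x)[39:63], k)
  ## white-noise SD shrinks by exactly sqrt(sum(w^2)) = sqrt(C(48,24)/2^48)
  set.seed(3)
  noise <- rnorm(2e5, 0, 2)
  shrink <- sqrt(choose(48, 24) / 2^48)
  expect_equal(sd(binomialSmooth(noise)), 2 * shrink, tolerance = 0.01)
  ## too-short input errors
  expect_error(binomialSmooth(rnorm(10)), "shorter")
})

test_that("amplitude rules accept and reject as specified", {
  ## 10 pA event over ~1 pA baseline noise: one accepted event
  tr <- eventTrace(onsets = 1, amps = 10, noise = 1, seed = 5)
  ev <- detectPscEvents(tr)
  acc <- ev[ev$status == "accepted", ]
  expect_equal(nrow(acc), 1)
  expect_equal(acc$peakAmplitude, 10, tolerance = 0.2 * 10)
  expect_equal(acc$onsetTime, 1, tolerance = 2e-3)

  ## 4.9 pA event never passes the 5 pA threshold (quiet baseline)
  tr2 <- eventTrace(onsets = 1, amps = 4.9, noise = 0.4, seed = 6)
  ev2 <- detectPscEvents(tr2)
  expect_false(any(ev2$status == "accepted"))
  expect_true(any(ev2$status == "rejected_amplitude"))

  ## 6 pA event on a baseline of SD 3: 2.5 x SD = 7.5 pA dominates
  n <- 40000
  v <- -20 + alternatingNoise(n, 3)
  t <- (seq_len(n) - 1) * 5e-5
  v <- v - 6 * pscKernel((t - 1) * 1000, 0.5, 4)
  tr3 <- Trace(v, dt = 5e-5, signalKind = "vc_current")
  ev3 <- detectPscEvents(tr3)
  expect_false(any(ev3$status == "accepted"))
  near <- ev3[abs(ev3$onsetTime - 1) < 5e-3, ]
  expect_true(all(near$status == "rejected_amplitude"))
})

test_that("kinetics are measured on the raw trace and gate acceptance", {
  ## noise-free biexponential (rise 0.5 / decay 4 ms): decay within 2%
  tr <- eventTrace(onsets = 1, amps = 20, riseTau = 0.5, decayTau = 4)
  ev <- detectPscEvents(tr)
  expect_equal(ev$status, "accepted")
  expect_equal(ev$decayTau, 4, tolerance = 0.02)
  expect_gt(ev$riseTime1090, 0)

  ## decay < 1 ms is discarded
  fast <- eventTrace(onsets = 1, amps = 20, riseTau = 0.15, decayTau = 0.8)
  evF <- detectPscEvents(fast)
  expect_equal(evF$status, "rejected_decay_lt_1ms")

  ## slow linear rise with decay 1.5 ms: decay < rise is discarded
  dt <- 5e-5
  n <- 40000
  t <- (seq_len(n) - 1) * dt
  shape <- numeric(n)
  riseIdx <- which(t >= 1 & t < 1.003)           # 3 ms linear rise
  shape[riseIdx] <- seq(0, 1, length.out = length(riseIdx))
  decIdx <- which(t >= 1.003)
  shape[decIdx] <- exp(-(t[decIdx] - 1.003) * 1000 / 1.5)
  v <- -20 - 20 * shape
  evS <- detectPscEvents(Trace(v, dt = dt, signalKind = "vc_current"))
  expect_true("rejected_decay_lt_rise" %in% evS$status)
  expect_false(any(evS$status == "accepted"))
})

test_that("every accepted event satisfies the acceptance invariant", {
  tr <- genSynapticTrace(eventGenSpec(
    rate = 4, amplitudeDist = list(name = "lognormal", meanlog = log(12),
                                   sdlog = 0.4),
    duration = 20), seed = 17)
  ev <- detectPscEvents(tr)
  acc <- ev[ev$status == "accepted", ]
  expect_gt(nrow(acc), 20)
  expect_true(all(acc$peakAmplitude >= 5))
  expect_true(all(acc$peakAmplitude >= 2.5 * acc$baselineSd))
  expect_true(all(acc$decayTau >= 1))
  expect_true(all(acc$decayTau >= acc$riseTime1090))
  ## every status is one of the defined outcomes (single rejection reason)
  expect_true(all(ev$status %in% c("accepted", "rejected_amplitude",
                                   "rejected_decay_lt_1ms",
                                   "rejected_decay_lt_rise",
                                   "rejected_fit")))
})

test_that("detection count is monotone in the amplitude threshold", {
  tr <- genSynapticTrace(eventGenSpec(
    rate = 4, amplitudeDist = list(name = "uniform", min = 5, max = 25),
    duration = 15), seed = 23)
  nAcc <- vapply(c(5, 7, 10, 15), function(th)
    sum(detectPscEvents(tr, ampThreshold = th)$status == "accepted"),
    numeric(1))
  expect_true(all(diff(nAcc) <= 0))
})

test_that("overlapping events are resolved on the decaying baseline", {
  ## second event 6 ms after the first, both large: two accepted events
  tr <- eventTrace(onsets = c(1, 1.006), amps = c(25, 20), noise = 1,
                   seed = 9)
  ev <- detectPscEvents(tr)
  acc <- ev[ev$status == "accepted", ]
  expect_equal(nrow(acc), 2)
  expect_equal(acc$onsetTime, c(1, 1.006), tolerance = 2e-3)
})

test_that("event trains compute IEIs and mean frequency as defined", {
  ev <- data.frame(onsetTime = c(1.0, 1.5, 2.5),
                   status = "accepted", peakAmplitude = 10)
  tn <- buildEventTrain(ev)
  expect_equal(tn$iei, c(0.5, 1.0))
  expect_equal(tn$meanFrequency, 1 / 0.75)       # 1.333... Hz
  ## single event: frequency undefined, flagged
  tn1 <- buildEventTrain(ev[1, ])
  expect_false(tn1$frequencyDefined)
  expect_true(is.na(tn1$meanFrequency))
  ## generator at 4 Hz for 100 s: frequency within 15%
  tr <- genSynapticTrace(eventGenSpec(
    rate = 4, amplitudeDist = list(name = "uniform", min = 10, max = 30),
    duration = 100), seed = 29)
  tn4 <- buildEventTrain(detectPscEvents(tr))
  expect_equal(tn4$meanFrequency, 4, tolerance = 0.15)
})
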