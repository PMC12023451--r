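---
title: "Methods: models, estimators and design choices in ephysflow"
author: "ephysflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in ephysflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephysflow)
```

# What the package computes

`ephysflow` implements the analysis chain of a combined slice-physiology and
olfactory-behaviour study design: whole-cell patch-clamp step protocols are
reduced to passive and active membrane properties, voltage-clamp recordings
of spontaneous postsynaptic currents (PSCs) are reduced to event tables,
per-cell event-property distributions are compared between groups (e.g.
wild-type vs knockout cohorts) with a per-cell balanced bootstrap and a
permutation Kolmogorov-Smirnov (KS) test, and go/no-go sessions are scored
into block performance and ROC/AUC discrimination indices.

Because raw recordings of this kind are rarely deposited, the package ships
first-class synthetic generators with attached ground truth; every estimator
is validated by parameter recovery against them.

Units: seconds internally, ms at reporting boundaries; mV, pA, M&#937;, pF,
fC. With these units `V[mV] = I[pA] * R[MOhm] * 1e-3` and
`tau[ms] = R[MOhm] * C[pF] * 1e-3`. Inward currents are negative; PSC
amplitudes are reported as positive magnitudes.

# Synthetic generators: what they emulate and what they do not

## Passive membrane responses

`genPassiveStepTraces()` solves a single-compartment RC membrane on the
sample grid. For piecewise-constant step stimuli the exponential update is
exact, so noise-free traces match the closed-form step response to machine
precision (the basis of the "numerical tolerance" recovery tests). Two modes
exist:

* **Current clamp**: voltage deflection `I * Rin` with time constant
  `Rin * Cm`, plus an optional sag. Sag is phenomenological -- a single slow
  relaxation (default time constant 150 ms) of the deflection back toward
  baseline -- not an explicit h-current model. Because the fast charging and
  the slow relaxation overlap in time, an internal relaxation amplitude `a`
  produces a *measured* sag ratio smaller than `a`. The generator therefore
  defines `sagFraction` at the protocol level: it numerically inverts the
  closed form so that a noise-free step of the protocol's duration shows
  exactly the requested `(Vss - Vpeak)/(Vbase - Vpeak)`. Ground truth and
  estimator then speak the same language.
* **Voltage clamp**: the same membrane accessed through a series resistance
  `Rs`; the command step produces a capacitive transient with initial
  amplitude `dV/Rs` relaxing to `dV/(Rs + Rm)` with time constant
  `Cm * (Rs || Rm)`. The onset sample carries the full peak (the solver
  evaluates the closed form at the step edge), which makes noise-free Rs
  recovery exact; real recordings band-limit this peak, which is why the
  noisy recovery tolerance is 10%.

## Stylised spiking

`genSpikingTraces()` is an intentionally stylised spike generator: its job is
to give the detectors a known answer, not to be biophysical. A step at or
above `rheobaseTrue` carries
`max(1, round(gainTrue * (I - rheobaseTrue) * duration))` spikes (capped by
the refractory period), placed evenly through the step. Each spike is a
template: a 2-ms ramp rising at 2.5 mV/ms into the threshold point, a linear
upstroke (~250 mV/ms) to `apPeak`, a repolarisation to
`thresholdTrue - fahpDepth`, and an exponential recovery. The ramp/upstroke
junction guarantees that the phase-plot rule (first dV/dt > 10 mV/ms) fires
exactly at `thresholdTrue`; the exact upstroke shape is otherwise arbitrary.

One consequence of the `>= 1 spike at rheobase` floor: when the rheobase
falls between coarse F-I grid points, the first non-zero F-I point is
floored to one spike and sits above the linear relation, biasing a gain fit
that includes it. This is a genuine property of count-based F-I curves, not
of the estimator; gain-recovery tests therefore use a rheobase commensurate
with the 50-pA grid.

## Synaptic event trains

`genSynapticTrace()` superposes unit-peak biexponential kernels
(`exp(-t/tau_decay) - exp(-t/tau_rise)`, normalised to peak 1) at Poisson
onset times on Gaussian baseline noise. Kernels are truncated at
20 decay time constants (relative error ~2e-9), keeping the additivity
invariant -- trace minus kernels equals the same-seed noise baseline --
testable to tight tolerance. The default amplitude distribution is
log-normal (median 10 pA, sdlog 0.35), matching the heavy right tail of PSC
amplitude histograms; normal (truncated at 1 pA), uniform and constant
distributions are available. Defaults (rate 4 Hz, rise 0.5 ms, decay 4 ms,
noise SD 2 pA) sit at the scales reported for spontaneous EPSCs in cortical
slices.

What the generator does *not* emulate: series-resistance filtering of event
kinetics, amplitude-kinetics correlations, bursting/non-Poisson timing, and
slow baseline drift. Passing recovery tests therefore demonstrate estimator
correctness under the stated statistical model, not robustness to every
pathology of real recordings.

## Behavioural sessions

`genSession()` builds blocks with exactly balanced CS+/CS- counts in
randomised order (the task's design), with per-block lick probabilities. Two
response models are available: an all-or-none responder (a trial is either a
full lick response in every 0.5-s interval or lick-free) -- the natural
reading of "lick probability per trial" -- and a graded model
(`gradedLicks = TRUE`) where each interval is an independent Bernoulli draw,
which exercises the graded interval-count ROC. Defaults follow the task
design: 10 blocks of 20 trials, four 0.5-s response intervals.

# Estimator choices

The acquisition literature leaves several windows unstated; the package
fixes them as follows (all configurable):

* **Baseline**: mean over the 50 ms before step onset. **Steady state**: the
  last 10% of the step.
* **Series resistance**: `Rs = dV / I_peak` per sweep; QC fails when the
  mean exceeds 30 M&#937; or the relative variation `(max - min)/min`
  exceeds 30%.
* **Capacitance**: per-step charge by trapezoidal integration of the
  transient (relative to the step's steady state) over 25 ms, then the
  least-squares slope of Q against V. The raw charge underestimates `Cm` by
  `(Rm/(Rs+Rm))^2` under realistic access resistance; since both `Rs` and
  `Rm` are measurable from the same sweeps, the default applies this
  correction (`correctRs = FALSE` reproduces the naive slope).
* **Time constant**: single exponential on the averaged response, fit window
  from 5% of the step duration after onset (skipping pipette transients) to
  five crude time constants. The asymptote is pinned to the measured steady
  state: with it free, the short window leaves the time constant and the
  asymptote poorly separated and the noisy-fit variance roughly doubles.
* **Sag**: default estimator `100 * (Vss - Vpeak)/(Vbase - Vpeak)` (a
  percentage, matching reported ~4% scales); the literal peak/steady-state
  deflection ratio (a number near 1) is available as `method = "ratio"` --
  the two definitions are not mutually consistent and the percentage form is
  the one on the reported scale. The peak is located on a 1-ms running mean
  so a single extreme noise sample cannot masquerade as sag; the null
  simulation (zero sag, 0.3 mV noise) stays below 1% absolute.
* **Spike detection**: upward 0-mV crossing with a 1-ms refractory merge,
  times at the peak.
* **AP threshold**: dV/dt by central differences on the raw grid, no
  smoothing (the phase-plot rule is threshold-sensitive to smoothing). The
  threshold is the first point of the contiguous dV/dt > 10 mV/ms run
  containing the upstroke maximum, found by a backward search from the
  fastest upstroke point. On clean upstrokes this is identical to the
  literal forward rule ("first point where dV/dt exceeds 10 mV/ms"), but it
  is immune to isolated noise crossings: at 0.3 mV sample noise the
  central-difference dV/dt has an SD of ~4 mV/ms, so a forward scan from
  stimulus onset would fire on baseline noise long before the spike.
* **F-I gain**: frequency is spikes per step divided by the step duration
  (0.5 s); the gain is the regression slope over the first k non-zero
  points, k chosen among {3, 4} by the better linear fit, and the chosen
  region is recorded.

# PSC detection

The detector follows the classic smooth-then-threshold design:

1. **Smoothing**: 25-coefficient binomial kernel (`choose(24, k)/2^24`),
   unit-sum and symmetric, applied with reflected edges. White noise of SD
   `s` shrinks to exactly `s * sqrt(choose(48, 24)/2^48)` (~0.34 s).
2. **Candidates**: local maxima of the rectified smoothed trace. Each peak
   is scored against a local "previous baseline": mean over a 10-ms window
   ending 1 ms before onset, excluding samples of earlier events when enough
   clean samples exist; the baseline SD is taken from the raw trace. The
   onset is the last baseline crossing before the peak. Acceptance requires
   a deflection of at least 5 pA *and* at least 2.5 baseline SDs (the rules
   are conjunctive). A discovery floor of `min(3 pA, 2 SD)` decides which
   sub-threshold peaks are even recorded (as `rejected_amplitude`); below
   that they are noise ripples, not events.
3. **Overlap**: a peak riding inside a previous event's span is scored
   against the valley between the two peaks (the local decaying baseline),
   so genuinely compound events are kept while decay-ripple artifacts fail
   the amplitude rules.
4. **Kinetics on the raw trace**: 10-90% rise time by linear interpolation;
   decay by a least-squares single exponential from 1 ms after the peak to
   90% recovery (truncated at the next onset). The 1-ms offset skips the
   residual rising component of the biexponential shape, which otherwise
   biases the fitted decay by a few percent; with it, a noise-free
   4-ms-decay kernel is recovered within 1%. Events with fitted decay < 1 ms
   or shorter than the rise time are discarded with the matching status;
   fits that fail or return non-physical constants (tau > 500 ms) are
   `rejected_fit`.
5. **Trains**: inter-event intervals between consecutive accepted onsets;
   mean frequency is the inverse of the mean interval; cells with fewer than
   two events are flagged with undefined frequency.

# Group statistics

`balancedResample()` draws the same number of events (default: the rounded
mean event count across cells; the study scale is 375 for sEPSC-like and
1000 for sIPSC-like data) with replacement from every cell, removing
per-cell sample-size bias. `bootstrapCpd()` averages empirical CDFs over
iterations (study scale 10,000; the result object records what was used).

`permutationKs()` reports the observed statistic as the mean +/- SD of the
two-sample KS D across balanced resamples (the "D = 0.09 +/- 0.01" style of
reporting). The null distribution repeats the *identical* computation on
shuffled data. Two design points deserve emphasis:

* **Shuffling unit**: by default all events are pooled and dealt back into
  pseudo-cells preserving every cell's event count (event-level shuffling);
  whole-cell label shuffling is available and is the conservative choice
  when between-cell correlation is suspected.
* **Null statistic**: each shuffle is processed through the same
  mean-over-iterations pipeline as the observed statistic
  (`nullStatistic = "mean_resampled"`). Under an exchangeable null the
  observed and null statistics are then exchangeable, which is what makes
  the p-value calibrated -- the type-I error at alpha = 0.05 lands in
  [0.03, 0.07] in simulation. A cheaper single-resample null
  (`"single"`) is offered; it compares a low-variance observed mean against
  high-variance null draws and is conservative.
* **p estimator**: add-one correction `(b + 1)/(m + 1)` by default, so p is
  never exactly zero; the plain proportion is available.

Package defaults use 1000 iterations/permutations so interactive runs finish
in seconds; analyses at the study scale should pass 10,000 explicitly.

# Behaviour

Trials are classified by the task's reward rule (licks in *every* 0.5-s
interval of a CS+ trial is a hit; the relaxed any-interval criterion is an
option). Invalid trials are excluded everywhere. The learning criterion is
85% correct in two blocks anywhere in the session by default; the stricter
three-consecutive-blocks reading is available because the two formulations
circulate side by side and neither is obviously canonical.

The ROC decision variable is the count of lick-positive intervals (0-4) --
the minimal graded score consistent with the lick-interval protocol; a
threshold sweep over it yields the ROC points, and the AUC by the
trapezoidal rule. All-or-none responders reduce to the single-point
trapezoid `(TPR + 1 - FPR)/2`. This AUC equals the normalised Mann-Whitney
U statistic with ties counted half, which is how the tests oracle it.
Windows ("first 60"/"last 60" trials) are taken over valid trials in
presentation order. AUC standard errors use the Hanley-McNeil closed form
with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; the group comparison
`z = (A1 - A2)/sqrt(se1^2 + se2^2)` assumes independent groups (different
animals), so the correlated-ROC variant is deliberately not implemented.

# Problem sizes and numerical tolerances in the shipped tests

The test suite validates at desk scale: parameter recovery uses single cells
per protocol at 20 kHz; event-detection sensitivity/FDR uses five 40-s
recordings at 4 Hz (about 800 true events); KS calibration uses 1000
exchangeable-null runs with 5 cells x 30 events per group, 10 resample
iterations and 199 permutations; CPD convergence uses 8 cells x 500 values
and 2000 iterations; chance-level behaviour uses 1000 sessions of 60 trials.
These sizes were chosen so that Monte-Carlo error sits comfortably inside
each stated tolerance (e.g. the 0.02 band on a mean AUC whose per-session SD
is ~0.065). The demo cohort (`makeDemoDataset()`) defaults to 12 cells per
group at 10 kHz -- the typical per-group n in studies of this design --
and is exercised in tests at reduced size.

# Known limitations

* The spiking generator's stylised waveform means half-width and fAHP
  recover template properties, not biophysics; they validate the measurement
  geometry only.
* The capacitance correction assumes the single-compartment access model;
  dendritic charge redistribution is outside the model.
* Event detection assumes stationary baseline noise; slow drift should be
  removed upstream.
* ABF/NWB ingestion is not implemented; the native fixture format is the
  CSV-plus-JSON-sidecar layout written by `writeSweepSet()`, which
  round-trips samples bit-exactly.
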