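---
title: "Models and methods behind whiskerVR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind whiskerVR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(whiskerVR)
```

This vignette is the package's own account of the models it implements:
the closed-loop session generator, the kinematic and event-alignment
computations, the response statistics, the habituation regression and
the population decoder — with the assumptions, defaults and numerical
choices a maintainer needs to judge them.

## The behavioural paradigm being modelled

A head-fixed mouse runs on a treadmill while whisking against a surface
whose rotation is yoked to locomotion, so self-motion generates a
predictable tactile flow.  After a set locomotor distance
(`trialDistance`, default 200 cm) the surface translates
`translationDistance` (default 1 cm) into rostral or caudal whisker
space, or stays at the centre, with configurable probabilities
(default equal thirds).  After a displaced epoch of the same distance
the surface returns to the centre.  A movement that brings the surface
into reach of a whisker that was not touching it is a gain of whisker
contact (GoW); one that removes a touching whisker is a loss (LoW).
Contact events are *external* when caused by surface motion and *self*
when caused by the animal resuming whisking against a stationary
surface.

## The synthetic session generator

The generator is first-class, tested code: its output carries complete
ground truth (event times, origins, repetition indices, per-neuron
generative parameters), which is what makes every downstream stage
testable as a parameter-recovery problem.

**Locomotion.** Alternating run/rest bouts with exponential lengths
(means `runBoutMean` = 25 s and `restBoutMean` = 4 s, floored at 1 s),
a mean running speed of 23.7 cm/s, an AR(1) within-bout fluctuation
(s.d. 3 cm/s, ~1 s correlation time) and 0.2 s Gaussian ramps at bout
edges.  The bout means are chosen so that running dominates the session
the way volitionally running mice do; the speed value is the
behavioural statistic the analysis assumes.

**Whisking.** A shared whisk cycle drives all whiskers: a sinusoid at
`whiskFreq` = 19 Hz whose frequency and amplitude are re-drawn each
cycle with multiplicative log-normal jitter (s.d. 0.04 and 0.1), active
during whisking bouts (means 20 s whisking / 2.5 s quiescent) and flat
at the setpoint otherwise.  A pure tone would be an unrealistically
narrow spectral line; per-cycle jitter keeps a stable ~19 Hz peak while
spreading power the way real whisking does.  Whisker setpoints track
the surface at `whiskSetpointTracking` = 4 °/cm (clamped at ±1.5
translation distances — an out-of-field surface is not tracked),
emulating the innate repositioning of whiskers toward a displaced
surface.

**Contact geometry.** Whisker *w* sweeps the angular interval
[setpoint − amplitude, setpoint + amplitude] while whisking; the
surface occupies an azimuth band of half-width 14° whose centre moves
12 °/cm of axial position.  Contact requires whisking and overlap of
sweep and band; with the default setpoints (60°, 90°, 120°) the centre
position touches only the middle whisker, a rostral excursion adds the
rostral whisker, a caudal excursion the caudal one, and returns remove
them — so both movement directions generate GoW events on different
whiskers and returns generate LoW events, while small in-span
translations change nothing.  Partial setpoint tracking (4 °/cm against
the band's 12 °/cm) is what leaves a net contact change after a
translation.

**Spike trains.** Each neuron is an inhomogeneous Poisson process
sampled by thinning with a 2 ms absolute refractory period (bursts of
unphysical inter-spike intervals would otherwise distort window
counts at high transient rates).  The rate is

\[
\lambda_i(t) = b_i + \sum_e s_e\, g_i\, K(t - t_e)\, a_e\,
\max\{0,\, 1 + h_i (r_e - 1)\} + g^{s}_i\, \mathrm{drive}(t),
\]

with baseline \(b_i\) (gamma across neurons, mean 8 spikes/s), a
peak-normalised difference-of-exponentials kernel \(K\) (latency 20 ms,
rise 10 ms, decay 60 ms), GoW/LoW polarity \(s_e \in \{+1,-1\}\),
origin factor \(a_e\) (1 for external, `self_attenuation` = 0.4 for
self events), fractional habituation slope \(h_i\) (default −0.02 per
external-GoW repetition, floored so the gain never goes negative) and
sustained gain \(g^{s}_i\).  The sustained drive is the contact
indicator relaxed with a 0.5 s time constant: the self-generated touch
response builds up over repeated whisks rather than stepping on, which
also keeps the sustained gain out of the transient window so the two
response classes remain statistically separable the way the window
classification assumes.  Negative excursions are floored at zero rate.

**Population defaults.**  `makeNeuronSpecs` assigns 67 % of neurons to
responsive classes (40/40/20 split between transient, sustained and
both), 55 % of responsive neurons an excitatory-GoW/suppressive-LoW
polarity (the remainder the opposite), attenuation 0.4 and habituation
−0.02 — the population statistics the analysis is designed to recover.
The recovery *experiments* (acceptance script, classification tests)
override the effect sizes to "strong": transient gain 120 spikes/s and
sustained gain 18 spikes/s, at least three baseline standard deviations
of a 300 ms window rate at 8 spikes/s, with uniform excitatory polarity
and no habituation, because those experiments measure the
classification and index machinery, not adaptation; habituation has its
own recovery experiments.

**Seeding.** One master seed fans out to named substreams (locomotion,
outcomes, whisking, spikes, tracks, decoding), so changing the number
of draws one component consumes never perturbs another, and full
sessions are byte-reproducible.

## Kinematics

Angles are measured per labelled point about a fixed face reference
point against the image's vertical axis (0° vertically above the face
point, positive rostral; image y grows downward).  The band-pass is a
4th-order Butterworth applied forward and backward
(`signal::filtfilt`), so touch-onset timing is not biased by filter
delay; gaps from missing labels are bridged by linear interpolation up
to 20 ms and left absent otherwise.  Curvature is the signed Menger
curvature 4·Area/(abc) of the three distal labels — the inverse
circumradius, signed by the orientation of the triple — reported in
1/mm via the configured pixel scale (`pxPerMm`, default 20 px/mm; the
camera calibration is a free parameter of any such analysis, so
curvature units are scale-dependent).  The curvature derivative is a
Savitzky–Golay first derivative of polynomial order 3 in a centred
100 ms window, which *is* the least-squares local cubic slope; edges
use truncated-window fits.  Whisk phase comes from the FFT analytic
signal of the band-passed angle, with phase 0 at the rostral peak and
protraction defined as phase in (−π, 0); traces with variance below
1e−6 get undefined phase rather than noise.

Touch detection thresholds |dκ/dt| at `k` = 5 median absolute
deviations of its no-contact distribution, requires the excursion to
persist 10 ms, merges onsets within 20 ms, and reports the onset as the
frame of peak |dκ/dt| within each suprathreshold run — the centred
derivative window otherwise anticipates the rise by up to half a
window.  These defaults were fixed once against simulator ground truth
(≥95 % of true onsets within ±10 ms on the test sessions) and are
exposed as arguments.

## Event alignment and windows

PSTH bins are half-open [t, t+Δ) so an event-time spike lands in the
first post-onset bin; rates are counts/(trials × width) and the stored
baseline statistics come from the 300 ms pre-movement window.  The
transient window is automated (the manual trough-marking such analyses
traditionally use is not reproducible): the peak is the maximum bin in
(0, 0.6] s; the window runs from the nearest preceding to the nearest
following weak local minimum that lies strictly below the peak
(plateaus at peak level are part of the response), clamped to
[0, 0.8] s, with a [0, 0.3] s fallback when no peak exceeds baseline
mean + 2 s.d.  The sustained window is 300 ms starting 1 s after the
transient window ends; modulation windows are 500 ms each side of
movement onset (both anchored at onset); GoW responses use 50 ms after
touch onset with a free-whisking window (−250 to −50 ms) as the
condition baseline.  Peri-event alignment uses a fixed [−1, +2] s
epoch, and events with another same-stream event inside their baseline
can be excluded with `cleanBaselineEvents`.

## Response statistics

`classifyNeuron` runs a one-way ANOVA across the three windows and
Tukey's HSD on the three pairwise contrasts at family α = 0.05:
sustained ⇔ baseline–sustained significant; transient ⇔
baseline–transient significant *and* the transient mean exceeds both
other means; both ⇔ both rules fire; otherwise nonresponsive.
Zero-variance inputs are exact ties and carry no evidence (label
nonresponsive, p = 1).  A minimum of 5 trials per window is enforced;
populations route through `classifyPopulation`, which excludes
under-sampled neurons explicitly.  The modulation index
(post − pre)/(post + pre) is defined as 0 when both rates are 0 (the
paperwork of the formula leaves 0/0 open; 0 is the only symmetric
choice).  The external-vs-self contrast uses the exact signed-rank
distribution for n ≤ 25 pairs and the normal approximation with
continuity correction above, dropping zero differences.

## Habituation

Drift screening compares baseline rates of the first 10 and last 10
trials with a two-sided Wilcoxon signed-rank test at α = 0.05, pairing
by trial order within block (1st with 1st, …).  Pairing sorted values
("by rank") was considered and rejected: differences of order
statistics are not i.i.d. symmetric under the null, which would break
the test's calibration — order pairing keeps the null rejection rate
near nominal, which the test suite verifies.  Repetition slopes are OLS
of windowed rate on repetition index; repetitions with no events are
gaps, not zeros; both raw and baseline-subtracted magnitudes are
computed, and the baseline-subtracted series feeds the slope tests.
The population test is a one-sided one-sample t-test of mean slope < 0.
Waveform-amplitude series (a spike-sorting stability check) are
range-normalised by min–max scaling; a constant series is
reported as "stable (degenerate range)" rather than an error.

When validating slope recovery, the expected value is the OLS slope of
the *noiseless* per-repetition series including the gain floor — for
steep generator slopes the factor max(0, 1 + h(k−1)) clamps at zero
within 30 repetitions and a pure linear extrapolation would be the
wrong oracle.  Across the grid {0, −0.01, −0.02, −0.04}/rep the suite
checks monotonicity and the joint through-origin calibration of median
fitted slopes against that oracle, because a per-cell criterion at
30 repetitions × 50 neurons sits inside the median's own sampling
noise for the smallest slope.

## Decoding

Features are per-neuron rates in 150 ms bins centred on each prediction
time, stepped every 20 ms (overlapping bins share spikes by
construction).  Z-scoring is fit on the training folds only and applied
to held-out data — scaling on the full set would leak test statistics
into training; under balanced designs the difference is small but the
safe variant costs nothing.  The classifier is a linear one-vs-rest
maximum-margin model (binary machines from `e1071::svm`, cost 1), with
ties in decision values broken toward the lowest class index; it is
pluggable behind a `fit`/`predict` contract.  Cross-validation is
stratified 10-fold with 50 resample runs (a resample is a fresh
stratified fold assignment), scored by zero-one loss; accuracy and its
s.e.m. over resamples are reported with chance = 1/number of classes.
Subpopulation decoding reuses identical trial splits (shared seed) so
transient and sustained curves are directly comparable.

## What the generator does and does not emulate

It reproduces the behavioural statistics (running speed, whisk rate,
trial protocol, outcome probabilities), the event taxonomy
(GoW/LoW × external/self × direction), and the response phenomenology
(transient kernels, sustained elevation, self-attenuation, linear
habituation, class mixtures).  It does not emulate video, tracking
noise beyond point jitter and contact bending, multi-whisker mechanical
interactions, slow electrode drift (except as an explicit test
construct), bursting or non-Poisson spiking statistics, or any
LoW-evoked suppression dynamics beyond a polarity flip.  Passing tests
therefore demonstrate that the analysis recovers known structure from
data obeying its assumptions — not that real recordings obey them.

## Problem sizes and runtime choices

The test suite and acceptance script run on one CPU in a few minutes by
simulating at the scales the statistics need rather than the recording
hardware's native ones: event-schedule experiments use a 200 frames/s
clock (the spike model's kernels are smooth at 5 ms resolution),
60-event classification experiments, 40 + 40 event modulation
experiments, 30-repetition habituation series and 50-neuron
populations; full closed-loop sessions for kinematics tests run 60 s at
the native 500 frames/s.  The decoder tests use 3 classes × 12–20
trials with 4–5 folds and 2–4 resamples; the full 10 × 50 default is
the analysis configuration, not the test configuration.

## Known limitations

- The surface translation's speed profile is not constrained by the
  paradigm (response magnitude is insensitive to it); a 250 ms linear
  ramp is the default and any smooth profile is acceptable.
- Touch detection assumes curvature bending is visible in the tracked
  labels; whiskers that slip past the surface without bending are
  invisible to it.
- The NWB import path is not provided; sessions enter through the
  plain-text directory format (`writeSession`/`readSession`), and
  external recordings must be mapped onto it.
- "Both"-class neurons are reported as such; downstream selections
  (e.g. transient-only decoding) must choose explicitly whether to
  include them, as `subpopulationDecode` does on both sides.
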