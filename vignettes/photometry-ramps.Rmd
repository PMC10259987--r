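---
title: "Methods: photometry ramps, stimulation plasticity, and approach hazard"
author: "phramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry ramps, stimulation plasticity, and approach hazard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phramp)
```

## What this package computes

`phramp` implements the signal-processing and statistical chain used to ask
whether striatal signals (dopamine release, cholinergic-interneuron calcium)
ramp up during motivated approach, whether optogenetically evoked dopamine
release shows short-term depression, and whether pharmacological blockade of
nicotinic or dopaminergic transmission suppresses the moment-to-moment
likelihood of initiating a trial. Every stage can be exercised on synthetic
sessions with known ground truth, so the statistical machinery is testable
without any recording hardware or animal data.

The chain is:

1. **Demultiplexing.** Acquisition interleaves LED excitation channels in
   10 ms frames (4 ms on, 6 ms off) on a single detector sampled at 10 kHz.
   `demultiplex()` averages the detector samples inside each on-window
   (discarding a 1 ms settling prefix) and timestamps the frame at the
   on-window center, giving one uniform trace per channel at
   `1 / (frame_len * n_channels)` Hz.
2. **Isosbestic correction.** `isosbestic_correct()` fits the 405 nm control
   channel onto the signal channel by ordinary least squares over the whole
   session and returns `dff = (signal - fitted) / fitted`.
3. **Alignment.** `align_trace()` builds trial x sample matrices on the
   trace's own grid (nearest frame, no resampling), with half-open windows
   `[-pre, +post)`.
4. **Shuffle-null statistics.** `shuffle_test()` compares the mean max–min
   ramp slope (0.5 s before approach completion) or the mean post-event peak
   (1 s after a reward click) against the 2.5th–97.5th percentile range of
   1000 random-time shuffles.
5. **Stimulation plasticity.** `summation_ratio()`, `paired_pulse_amplitudes()`
   and the repeated-measures ANOVAs quantify dose–response and
   short-term-depression structure of evoked responses.
6. **Behavior / pharmacology.** `hazard_rate()`, `latency_cdf()`,
   `per_bin_condition_test()` and `condition_anova()` implement the
   trial-initiation analyses at 250 ms bins with a 1 s long-latency filter.

## The synthetic-data generator

The generator (`synth_config()`, `generate_pavlovian_session()`,
`generate_stim_session()`, `generate_spike_train()`,
`generate_pharm_latencies()`) is first-class, tested code. It emulates:

* **Bleaching** — one multiplicative exponential, shared by all channels.
  Default time constant 3600 s: slow photobleaching on the scale of a
  multi-hour behavioral session, so that within a session motion artifacts,
  not bleaching, dominate raw-channel variance (which is also the regime in
  which an isosbestic control is most informative).
* **Shared motion** — a low-pass (~2 Hz cutoff) Gaussian process injected
  multiplicatively and *identically* into signal and isosbestic channels
  (default SD 3% of baseline). The correction is only testable if a shared
  artifact exists.
* **Click transients** — a difference-of-exponentials kernel (rise 50 ms,
  decay 500 ms, unit peak, default amplitude 0.05 dF/F), resembling
  published dopamine-sensor kinetics without claiming to match any
  particular figure.
* **Approach ramps** — a linear ramp of configurable slope ending exactly at
  each food-port entry. The ramp always spans the full `ramp_duration`
  (default 1 s), even when the collection latency is shorter, so ground
  truth is exactly linear over the 0.5 s analysis window on every trial; it
  releases with the kernel's decay constant after the port entry.
* **Collection latencies** — lognormal(meanlog 0.7, sdlog 0.6) s by default,
  so that both fast (<1 s) and slow (>2 s) collections occur; this is what
  lets the click response be dissociated from the approach ramp. The
  distributional form is a modeling stand-in: the behavioral literature
  gives no parametric form for these latencies.
* **Evoked responses** — each laser pulse contributes the kernel scaled by
  pulse width (linear, normalized to 4 ms) and by a depression state `s`:
  `s` is multiplied by `1 - depression_factor` at each pulse and recovers
  toward 1 with `depression_recovery_tau`. `depression_factor = 0` makes the
  generator exactly linear (shift-invariant and additive), which is the
  regime the linear-summation analysis must identify with a ratio of 1.
* **Spike trains** — inhomogeneous-Poisson thinning around a base rate, with
  an optional linear rate ramp before each approach-completion event.
* **Initiation latencies** — discrete-time hazard sampling at 250 ms bins:
  baseline per-bin hazard 0.15, multiplied by a per-condition, per-bin
  profile. Observation is capped at 10 s (a pragmatic cap; uninitiated
  trials are recorded censored there).

One global RNG stream per session is split into named substreams (events,
latencies, motion, noise, spikes, hazard), so turning one component off
never perturbs the others — sessions differing only in noise share their
event schedule exactly.

What the generator does **not** emulate: sensor nonlinearity and saturation,
hemodynamic or spectral crosstalk between channels, non-stationary motion
statistics, receptor desensitization kinetics (depression is
phenomenological), and any model of choice behavior. Passing tests therefore
demonstrate that the *machinery* is correct and calibrated on data obeying
these idealizations, not that real recordings satisfy them.

## Numerical and statistical conventions

* **Max–min slope.** `(s[argmax] - s[argmin]) / (t[argmax] - t[argmin])`
  over the 0.5 s window ending at the event; first occurrences win ties; a
  constant segment has slope 0. The vectorized implementation is tested
  against a brute-force scan on random segments.
* **Shuffle null.** Each shuffle draws as many pseudo-events as there are
  real events, uniformly over the session with window-sized margins, and
  the null statistic is the *mean* over that pseudo-event set (the analyses
  compare session-level means). A per-event null is available via
  `per_event_null = TRUE`. Pseudo-events are drawn without exclusion zones
  around real events. Significance is two-sided at 95% (outside the
  2.5–97.5 percentile range); direction is reported separately, so ramping
  *down* is distinguishable from ramping up. No multiple-comparison
  correction is applied across recordings: tallies are per-recording calls
  by design.
* **Long-latency filter.** Slope analyses at approach completion use trials
  whose initiating event is more than 1 s earlier (`min_latency = 1`),
  separating cue-evoked transients from approach-related ramping. The
  shuffle-coverage experiments use the same convention.
* **Isosbestic fit.** One OLS fit over the whole session, not windowed; slow
  bleaching common to both channels is absorbed by the fit. This is a known
  simplification — a signal channel that bleaches at a grossly different
  rate than the control would leave a residual trend.
* **z-scoring** uses the population SD (divisor `n`), the usual convention
  for signal normalization.
* **Latency bins** are right-closed: a latency of exactly 2.0 s belongs to
  the bin ending at 2.0 s. The hazard estimator is
  `events_in_bin / at_risk`, with censored trials leaving the risk set
  without counting as events; the CDF reconstructed as
  `1 - prod(1 - h)` equals the direct empirical CDF bin-for-bin.
* **Per-bin condition test.** The per-bin significance marks on hazard/CDF
  curves are produced by a within-subject label-permutation test
  (assumption-free, matching the repeated-measures design; the two-sided
  p-value uses the `(1+k)/(1+B)` estimator). Bin-wise tests are
  deliberately uncorrected, matching per-bin significance marks on the
  corresponding figures. Rows are canonicalized before permuting so the
  flags do not depend on input row order.
* **Repeated-measures ANOVA** is computed through `stats::aov()` with the
  subject term (one-way) or `Error(subject/(A*B))` strata (two-way); mean
  squares that are numerically zero relative to the data scale are treated
  as exact zeros so constant tables return F = 0. Holm-corrected paired
  t-tests against vehicle serve as post-hocs — only vehicle-vs-drug
  contrasts are of interest, so Holm is preferred over Tukey.
* **Summation prediction.** The predicted train response is the sum of
  `n_pulses` copies of the single-pulse response shifted by `1/frequency`.
  Shifts are integer numbers of samples; at the 10 kHz ground-truth rate the
  standard frequencies (4, 8, 16 Hz) are exactly commensurate. The
  paired-pulse analysis scales the template to the measured first-pulse
  amplitude before subtraction, to accommodate slow session-level amplitude
  drift.

## Problem sizes used in the validation experiments

The package's own validation (the test suite and `scripts/acceptance.R`)
uses 300 s Pavlovian sessions (about 13 clicks at 15–30 s intervals), 200
replicate sessions for the shuffle-coverage experiment, 1000 shuffles per
test, 10,000 trials for hazard closed-form checks, and 4000 trials per
condition for the hazard-recovery and per-bin-flagging experiments. These
sizes were chosen so that each experiment's binomial/sampling tolerance is
small compared to the effect being checked.

Two experiment-design notes. Null sessions for the shuffle-coverage
experiment are generated with *no* event-locked signal at all (ramp slope
and transient amplitude zero) while keeping bleaching, shared motion and
detector noise: coverage is a property of the null calibration of the
statistic, so the H0 sessions must actually satisfy H0 for the tested
windows. The motion-rejection experiment conversely keeps the click
transients but omits ramps: default-size approach ramps (peaking at
0.5 dF/F) would dominate raw signal-channel variance and mask the
motion correlation that the experiment is about, without changing the
correction being tested.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(session_duration = 300, seed = 1)
sess <- generate_pavlovian_session(cfg)
chans <- demultiplex(sess$raw, sess$schedule)
dff <- isosbestic_correct(chans$green_565, chans$violet_405)

lat <- extract_latencies(sess$events, "click", "food_port_in", min_latency = 1)
portin <- sess$events$time_s[sess$events$event_type == "food_port_in" &
                             sess$events$trial_id %in% lat$trial_id]
shuffle_test(dff, portin, "maxmin_slope", window = 0.5,
             n_shuffles = 1000, seed = 2)
```

## Known limitations

* The whole-session OLS isosbestic fit removes shared multiplicative
  artifacts to first order only; quadratic residuals of large motion events
  survive at a small amplitude.
* Frame-level alignment (no interpolation) quantizes event times to the
  ~20–30 ms frame grid; this is deliberate (resampling would manufacture
  smoothness that the shuffle statistics could then exploit) but makes
  sub-frame latencies invisible.
* Spike-rate smoothing (Gaussian SD 100 ms on a 100 Hz grid, whole-session)
  loses kernel mass for spikes within the kernel half-width of the session
  edges.
* The completed-trial definition treats a `timeout` event as the sole
  disqualifier of an otherwise well-formed trial sequence.
* Laser power and drug dose are carried as metadata labels only and never
  enter computation.
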