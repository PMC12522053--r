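---
title: "Detecting venous air embolism from chest impedance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting venous air embolism from chest impedance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 3.5)
library(vaemonitor)
```

## The monitoring problem

Venous air embolism (VAE) — entrainment of air into the venous circulation —
is a feared intraoperative complication, particularly in neurosurgery in the
sitting position. The standard detection tools (transoesophageal
echocardiography, precordial Doppler) are operator-dependent and provide no
automated alarm. Transthoracic electrical impedance offers a cheap,
continuous alternative signal: a 20–100 kHz carrier is driven across the
chest and the measured impedance varies chiefly with lung air volume.
Intrathoracic air from an embolus raises impedance too, which suggests two
detectable signatures:

1. **Blips** — rapid, brief impedance rises (seconds or less) from a large
   air bolus passing the sensed volume; and
2. **Gradual paired rises** — slow entrainment lifting the whole
   respiratory impedance waveform, i.e. matched increases in both
   end-inspiratory impedance (EII) and end-expiratory impedance (EEI)
   against stable respiratory variation.

The magnitudes involved set the difficulty of the problem: respiratory
variation spans roughly 5–10 Ω while clinically significant entrainment
produces rises on the order of 0.01–1 Ω, so detection must separate a small
common-mode shift from a much larger periodic carrier, in the presence of
surgical artifact.

`vaemonitor` implements this analysis end to end: acquisition (voltage-divider
conversion, block-averaged sampling, a plain-text trace format), respiratory
cycle tracking, dual-modality detection with ventilator-maneuver
discrimination, a signal quality index (SQI) gating the alarms, a streaming
mode, and a seeded waveform simulator that generates every study condition
the tests exercise.

## Respiratory cycle tracking

The pipeline assumes each analysis window is either ventilated (a plausible
respiratory waveform is present) or not; everything downstream branches on
that decision.

**Smoothing.** A time-delayed (trailing) running average over 0.5 s removes
sample-level noise before peak detection. The causal window delays the
reported waveform by about a quarter second; since every comparison is made
between quantities smoothed identically, this delay cancels. The window is
deliberately short so it does not blunt bolus blips — which the blip
detector in any case reads from the unsmoothed trace.

**Peak detection.** End-inspiratory peaks are found by continuous wavelet
transform ridge detection: Ricker (Mexican-hat) wavelets at 16
logarithmically spaced scales spanning breath periods of 2–10 s, per-scale
local maxima linked into ridge lines across scales, and ridges that persist
over at least half the scales with adequate coefficient signal-to-noise kept
as peaks. This is markedly more robust to noise than raw extrema: a peak
must be supported coherently at many scales rather than at one sample.
Detected peaks are snapped to the local waveform maximum, peaks closer than
the minimum period are merged (keeping the higher; ties toward the earlier),
and peaks standing much lower above their neighbouring troughs than the
typical peak (below a quarter of the median prominence) are discarded —
without that last filter, small noise bumps inside long expiratory pauses
can fabricate a plausible-looking rate for very slow ventilation.

**Rate validation.** A peak train counts as ventilation when it has at
least three peaks, its median inter-peak interval lies in the surgical band
of 6–30 breaths/min (2–10 s periods, with a 3% edge allowance so detection
jitter cannot disqualify a signal sitting exactly on a boundary), and the
intervals are regular (MAD ≤ 25% of the median interval). Two further gates
protect against a subtle failure: band-pass filtering makes even white noise
quasi-periodic at breath-period scales, so interval statistics alone accept
pure noise. The median per-cycle excursion must therefore also reach 1 Ω
and stand four noise sigmas above the high-frequency noise floor (the noise
floor is estimated robustly from the median absolute successive difference
of the raw trace).

**Segmentation and robust summaries.** Cycle boundaries are placed at the
troughs between consecutive validated peaks, so each cycle contains exactly
one end-inspiratory peak; boundaries are anchored to the *first* sample
reaching the local minimum (within 2% of the cycle range) because when
expiration ends in a flat pause the literal argmin wanders over the pause
with the noise, which would jitter cycle composition and hence every
percentile summary. Within each half-open cycle the package computes the
minimum, maximum and the 25th/75th percentile values (linear interpolation
between order statistics). The percentiles serve as robust EEI and EII
estimates: unlike the raw extrema they are nearly immune to brief spikes,
and their agreement with the extrema is itself a quality signal (see SQI).
The mapping — EEI from the 25th percentile, EII from the 75th — follows
from inspiration raising chest impedance.

## Detection

**Cycle comparison.** Each cycle's EEI/EII pair is compared with the
previous cycle's against a trend threshold τ (default 0.1 Ω, inside the
0.01–1 Ω clinical scale). Both rising beyond τ is classified
`vae_or_peep`; an isolated EII change is `tv_change` (a tidal-volume change
moves only the end-inspiratory level); an isolated EEI rise is
`peep_tv_edge` (the uncommon PEEP-up/TV-down combination); anything else is
`stable`. The PEEP ambiguity is deliberately surfaced, not resolved: a
paired rise means "air entrainment or a PEEP change", and the classification
string says so.

**Trend accumulation.** The trend component accumulates evidence of a
sustained paired rise across cycles and across analysis windows: the length
of the consecutive `vae_or_peep` run, and a cumulative common-mode tracker
summing `min(d_EEI, d_EII)` per cycle (floored at zero so negative drift
cannot bank a deficit). Equivocal cycles hold the run — a pause in
entrainment is not evidence against it — while a paired *fall* beyond τ
resets it. One wrinkle matters in practice: a level change landing
mid-cycle splits across two adjacent comparisons, because the straddling
cycle's 75th percentile responds in the cycle containing the change while
its 25th percentile (sitting in the end-expiratory pause) responds one
cycle later. An isolated EII rise immediately followed by a complementary
isolated EEI rise is therefore fused into a single paired rise; without
this, a ventilated sustained step would be misread as a tidal-volume change
followed by a PEEP edge and never alarm.

The component saturates at a run of 8 cycles or a cumulative paired rise of
0.7 Ω, whichever is reached first, so with the default alarm threshold of
50 the alarm corresponds to 4 consecutive paired-rise cycles *or* a
confirmed 0.35 Ω common-mode rise. The rise saturation was set with the
segmentation geometry in mind: the last breath before a window edge never
yields a completed cycle (its closing trough arrives with the next breath),
so the evidence visible at a window end lags truth by roughly one breath;
0.35 Ω keeps a slow 1 Ω/30 s ramp detectable within about six breaths of
onset while remaining more than threefold the per-cycle threshold τ and two
orders of magnitude above the percentile jitter of clean signals (measured
false-alarm margin: peak confounder scores below 5 against a threshold of
50).

**Blips.** The raw trace is compared against a rolling-median baseline
(window: two median cycle lengths); maximal runs where the residual exceeds
`blip_k = 1.5` times the local respiratory excursion above the
end-expiratory level (median of `z_max − z_p25`; with an end-expiratory
pause the crest of a normal breath rides nearly the full excursion above
the rolling median, so the half-range would be far too permissive) are blip
candidates. Runs shorter than 0.15 s are chatter; runs longer than 3 s are
not blips and are left to the trend and absolute paths — the rolling median
itself absorbs sustained shifts. Onset and offset are refined to the
10%-of-rise crossing above the local pre-event level, walking only while
the edge stays monotone (so the walk stops at the respiratory waveform
instead of riding down it) and reporting the outer bracketing samples; on
simulated boluses at twice the respiratory excursion this recovers onsets
to within two samples at 100 Hz.

**Absolute rise (the unventilated path).** Without ventilation there are no
cycles to compare — precisely the circulation-without-ventilation situation
in which a cadaveric air injection still must alarm. The median impedance
of the most recent 10 s is compared against a slowly adapting reference
baseline (EMA, frozen while a candidate rise is in progress so the rise is
not absorbed); a sustained rise of 1 Ω maps exactly to the alarm threshold.
Window medians make this path inherently blind to brief excursions, which
are the blip detector's job.

**Score and alarm.** The window score is the maximum of the three
components, each scaled 0–100. Max, not sum: the modalities are alternative
readings of the same physical event, and summing would double-count. The
alarm raises at score ≥ 50 provided the SQI permits, and clears only after
two consecutive quiet windows (hysteresis against flapping). The absolute
path overrides the SQI gate: it exists exactly for signals whose SQI is
necessarily poor because no respiratory waveform is present. When a score
crosses the threshold but quality vetoes it, the assessment is flagged
`suppressed_low_sqi` rather than silently dropped.

## The signal quality index

The SQI is a heuristic weighted mean of five components in [0, 1]:
presence of a validated respiratory waveform (weight 0.35), inter-peak
regularity (0.2), respiratory amplitude versus the noise floor (0.2),
agreement of the percentile summaries with the raw extrema (0.1), and
stability of the per-cycle EEI/EII series across the window (0.15). The
weights mirror the ranking of contributors described above — waveform
detection and consistency dominate — and are config-exposed. The
robustness component compares the mean fractional gap
`((p25 − min) + (max − p75)) / range` with the value an ideal sinusoidal
cycle would give (`1 − √2/2 ≈ 0.293`), penalising only *excess* gap, i.e.
extrema inflated by spikes relative to the robust percentiles. Alarms are
suppressed below an SQI floor of 0.3.

Because every estimator in the SQI is deliberately robust (medians, MADs),
short high-amplitude artifact bursts — electrocautery — lower the index
only modestly; they are designed to be *survived*, not to disable
monitoring. Irregular hand ventilation, by contrast, degrades regularity
and consistency directly and pushes the index down, which matches its role
as the known failure mode of cycle-based analysis.

## The waveform simulator

Every test condition is generated by `simulate_trace()`:
`baseline + respiratory carrier + events + white Gaussian noise`, returning
the trace, a ground-truth event log with exact timings, and the noise-free
additive decomposition so tests can verify that each confounder touches
only its own term. Defaults are the study conditions used throughout:
100 Hz sampling (the instrument convention of many raw samples block-averaged
every 10 ms), 250 Ω baseline, 12 breaths/min, 7 Ω peak-to-peak respiratory
excursion (mid-range of the 5–10 Ω typical span), 0.1 Ω noise sigma.

The default carrier is a skewed raised cosine: inspiration over 35% of the
cycle, expiration over 25%, then an end-expiratory pause at baseline for
the final 40% — an I:E ratio near 1:2 with passive exhalation faster than
insufflation. The pause is not cosmetic: because more than a quarter of
each cycle rests at the end-expiratory level, the 25th percentile estimates
that level and a tidal-volume (amplitude) change moves only the
end-inspiratory summary. This is the physiological property the
maneuver-discrimination logic relies on; a pure sinusoid (retained as
`resp_shape = "sinusoid"` for analytic tests) does not have it, and with a
sinusoidal carrier an amplitude change shifts both percentiles.

Events: `blip` (smoothed rectangular pulse, 0.04 s edges), `ramp` (linear
rise then hold — gradual entrainment), `baseline_step`/`peep_step`
(additive sustained steps), `tv_step` (multiplies the carrier only),
`cautery_burst` (20× noise over an interval), `irregular_ventilation`
(per-breath lognormal period jitter and amplitude jitter), and
`apnea_interval`. Contradictory overlaps (apnoea under a tidal-volume
change) are rejected. The generator is a pure function of its arguments
including the seed, and restores the caller's RNG state.

What the simulator does **not** emulate: cardiogenic oscillations, electrode
motion artifact with structure (only stationary and gated Gaussian noise),
baseline wander unrelated to events, and the electrical physics of the
thorax. Passing tests therefore demonstrate that the algorithm implements
its stated contracts under the assumed signal model, not clinical
performance; the approach itself remains at the proof-of-concept stage.

## Numerical and design choices

* **Percentile definition:** linear interpolation between order statistics
  (type 7), pinned by a brute-force sort-and-interpolate oracle in the
  tests.
* **Windowing:** 30 s windows with 50% overlap; windows shorter than 10 s
  are withheld as warm-up; a trailing partial window is analysed when at
  least 10 s long. Streaming analysis buffers chunks and emits windows with
  identical sequential state threading, so stream output is byte-identical
  to batch output on the same trace.
* **Determinism:** analyses of fixed inputs involve no randomness at all;
  report floats are serialised at 6 significant digits with fixed key
  order, so repeated runs diff clean.
* **Ties and degenerate inputs:** merged close peaks keep the earlier on a
  tie; empty traces, constant traces (no extrema → no peaks → invalid),
  and cycles with zero range (amplitude and robustness components zero)
  all have defined behaviour exercised by tests.
* **Problem sizes in the test-suite:** property checks run at desk scale —
  60–120 s traces, 100-seed batteries for the sensitivity/specificity
  properties, 20-seed medians for SQI curves — sizes at which every
  measured margin (alarm latency, false-alarm scores, onset errors) is
  stable across reruns.

## Known limitations

* The trend path needs roughly a breath of latency per cycle comparison
  plus the window-edge segmentation lag; entrainment slower than about
  0.03 Ω per cycle will accumulate correspondingly slowly.
* A genuine PEEP increase is indistinguishable from entrainment by design
  (`vae_or_peep`); the alarm fires and the classification string carries
  the ambiguity.
* Sub-threshold but real paired drift (e.g. slow systemic volume change)
  accumulates in the common-mode tracker and will eventually alarm; on the
  0.01–1 Ω clinical scale this is arguably correct behaviour, but it means
  the package alarms on *any* sustained paired rise, whatever its cause.
* The SQI is heuristic. Its scale, weights and floor have no clinical
  calibration; they order signal conditions sensibly (clean > cautery >
  noise) and gate alarms, nothing more.

## A worked example

```{r example}
sim <- simulate_trace(
  duration_s = 120, noise_sigma_ohm = 0.2, seed = 1001,
  events = list(sim_event("ramp", t_start = 45, duration_s = 60, magnitude = 2))
)
analysis <- analyze_trace(sim$trace)
glance(analysis)
tidy(analysis)[, c("t_window", "score", "trend_component", "alarm", "sqi")]
```

```{r plots}
autoplot(analysis)
cycles <- respiratory_cycles(sim$trace)
plot_cycles(smooth_trace(sim$trace), cycles)
```
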