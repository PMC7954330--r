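---
title: "Synthetic paired field-potential recordings and the cross-correlation synchronization statistic"
author: "fieldsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fieldsync methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldsync)
```

## The scientific problem

In hippocampal slices perfused with AMPA, NMDA and GABA-A antagonists
("synaptic blockers" aCSF), spontaneous epileptiform discharges appear
simultaneously in areas CA3 and CA1 — second-long, millivolt-scale field
events, sometimes organized into tens-of-seconds bursts led by a
large-amplitude event. The degree to which the two regions discharge
together is quantified by a cross-correlation statistic between the
paired field-potential recordings, and pharmacological or surgical
manipulations (Cd²⁺, a CA3/CA1 cut, cholinergic antagonists, induced
seizure-like activity) are read out as changes in that statistic and in
the discharge statistics themselves.

No raw traces accompany the study this package emulates; what is
reproducible are the *summary statistics* each condition is reported to
show. `fieldsync` therefore ships a synthetic-data generator whose
presets encode those statistics, alongside the full analysis pipeline —
event detection, burst grouping, the synchronization score and the
statistical comparison protocol — so that every stage can be validated
on recordings with known ground truth.

## The generator

A recording is an annotated event train rendered through waveform
templates plus a two-band noise model. Under the default
(synaptic-blockers) preset:

* **Single discharges** follow a renewal process: exponential
  inter-event intervals above a 2 s refractory floor, with the mean gap
  set so the rate is 2.36 min⁻¹. Durations are drawn from a truncated
  normal (mean 1.07 s, SD 0.34 s); amplitudes are log-normal
  (CA3 mean 2.5 mV) with a floor that keeps every event well above the
  detection threshold at the default SNR.
* **Bursts** are a per-slice trait (probability 0.48). A bursting slice
  receives bursts at 0.375 min⁻¹; each is a large-amplitude leader
  (×2) followed by a regular train at the drawn intraburst frequency
  (truncated normal, mean 0.52 Hz, floor 0.30 Hz — the floor is the
  detectability limit of the 4-s grouping gap) filling the drawn burst
  duration (mean 35.61 s). Background singles are suppressed within the
  groupable margin (±4.5 s) of a burst so the burst statistics stay
  clean.
* **Coupling**: each CA3 discharge is copied to CA1 with probability
  0.85 at a 5 ms delay with 30 ms jitter; the copy's amplitude is the
  source amplitude rescaled to the CA1 channel mean and decorrelated by
  a log-normal factor (CV 0.85), with its own duration. These three
  parameters are the calibration levers for the synchronization score
  (below).
* **Population spikes** (50 ms, ~1 mV) occur independently per channel,
  CA1-dominant under the default preset and channel-symmetric and dense
  in the nonsynaptic (`low_ca`) preset.
* **Drug block**: blocked presets draw an onset — immediate with the
  preset's probability (10/22 for the Cd²⁺ preset), otherwise a
  truncated-normal latency (mean 4.09 min, SD 2.60 min). Discharges with
  onsets after the block are removed from both channels; population
  spikes persist.
* **Seizure-like activity (SLA)**: the bicuculline and 4-AP presets
  replace the renewal/burst process with a regular train (0.13 Hz and
  0.36 Hz respectively; 10% interval jitter) carrying the reported
  per-channel amplitudes.
* **Intracellular channel**: one biexponential conductance transient
  (rise 3 ms, decay 50 ms) per CA1 discharge, with peak conductance
  drawn log-normally so that at a −70 mV holding potential the
  peak-current distribution has mean 51.60 pA and SD 22.71 pA. The
  current is conductance × driving force `(V_hold − E_rev)` with
  `E_rev = 0` (the nicotinic-response reversal), so it scales exactly
  linearly with the holding potential and vanishes, pre-noise, at 0 mV.
  Recording noise (14.89 pA) reproduces the near-zero scatter observed
  at the reversal potential.

**Truncated draws preserve the printed mean.** Wherever a reported mean
describes an intrinsically positive quantity (durations, latencies,
frequencies), the sampler solves for the location parameter of the
truncated normal such that the *realized* mean equals the nominal one.
A naive `Normal(4.09, 2.60)` truncated at zero would have mean
4.41 min; the reported 4.09 min is the empirical mean of the observed
delays, so that is what the generator reproduces.

**Waveform template and the duration convention.** A discharge is a
negative-going difference of exponentials (rise constant 20 ms; decay
solved per event). The template's nominal duration is *defined* as its
width above a fixed reference level (0.36 mV by default — half the
detector's typical realized threshold): the decay constant is chosen so
the waveform crosses that level exactly at the drawn duration. This
makes half-threshold-crossing durations measured by the detector
unbiased estimators of ground-truth durations, which is what lets a
threshold detector recover the 1.07 s mean without per-event tuning.
The reference level was fixed once against the default noise model and
is a preset field (`duration_ref_mv`), not a detector input.

**Noise model.** Two bands, each scaled to an exact SD: a broadband
floor (white noise low-passed at 100 Hz, 0.03 mV) and a slow,
channel-independent baseline wander (low-passed at 1 Hz, 0.17 mV). The
wander is what keeps the cross-correlation of even perfectly coupled
recordings away from 1: it adds variance that the 50 Hz analysis filter
does not remove, but it is slow enough that the detector's running
median and robust threshold are barely disturbed.

**Determinism.** `(spec, duration, seed)` fully determines every
sample; cohorts derive per-slice child seeds through a documented
integer hash, so any slice can be regenerated in isolation. The RNG
state of the caller is saved and restored.

## Event detection

The detection conventions are this package's own (the emulated study
reports event statistics but not its detection criteria):

* baseline: running median, 90 s window, evaluated on a 20 Hz grid and
  interpolated. The window must be long compared to a burst: with a
  short window the median dives toward the event level inside a burst
  (~50% duty) and distorts the residual.
* threshold: 5× a robust noise scale — the lower quartile of 10-s-chunk
  MADs of the residual, so that slices spending much of the record in
  bursts still estimate their noise from quiet stretches — with an
  absolute floor of 0.65 mV.
* events: supra-threshold excursions of |residual|, with boundaries at
  the half-threshold crossings of a lightly smoothed (40 Hz) envelope;
  half-threshold segments are merged across gaps < 0.2 s before the
  full-threshold test (a raw first-crossing rule systematically
  truncates shallow decays — a first-passage bias). Events shorter than
  0.02 s are discarded; shorter than 0.1 s are population spikes;
  otherwise discharges.
* bursts: runs of ≥ 4 discharges with onset gaps < 4 s. The canonical
  minimum of 3 admits, at a 2.36 min⁻¹ background rate, a chance triple
  of sub-4-s gaps every few slices; those ~6 s pseudo-trains contaminate
  the burst statistics, while real trains carry ≥ ~10 events. Burst
  duration is last offset − first onset; intraburst frequency is
  (n − 1) over the *onset span*, the unbiased rate estimator for a
  regular train (dividing by the offset-based duration is biased low by
  one event duration).
* the single-discharge rate is reported per minute of *non-burst* time,
  since bursts occupy time in which background singles cannot occur.

## The synchronization statistic

`sync_score()` runs the four-stage pipeline:

1. anti-aliased decimation to 1 kHz (a zero-phase Gaussian anti-alias
   filter at a quarter of the target rate followed by integer
   subsampling — kept zero-phase deliberately, so no stage shifts the
   lag axis);
2. zero-phase Gaussian low-pass with half-gain at 50 Hz. The kernel's
   width follows in closed form from the half-gain convention:
   gain(f) = exp(−2π²σ²f²), σ = √(ln 2 / (2π² f_c²)) — making the
   filter bit-reproducible; edges are reflected;
3. Pearson-normalized cross-correlation of the mean-subtracted traces,
   normalized per lag by the overlap length, restricted to |lag| ≤ 1 s.
   Positive lag means CA1 lags CA3; identical traces give exactly 1 at
   zero lag;
4. Lowess smoothing over the lag axis (tricube weights, one robustness
   iteration, span 0.01 of the lag points), then the score = the
   maximum of the smoothed function, ties broken toward the smallest
   |lag|.

"First maximum" is read as the *global* maximum of the smoothed
function within the lag window: on the unimodal cross-correlation
functions this pipeline produces, the global and the first-local-peak
readings coincide, and the global reading is the robust one on noisy,
near-flat functions. Recordings shorter than 300 s are refused unless
explicitly overridden (with a warning); the whole record (or a chosen
window) is correlated at once rather than averaged over sub-windows.

**Calibration.** With the default preset the population mean score over
25 slices sits inside 0.47 ± 0.17, the reported band for synchronized
recordings — by construction, not by biology: coupling failure (0.15),
per-event amplitude decorrelation (CV 0.85), 30 ms jitter and the
uncorrelated wander together set the score's ceiling, and were tuned
once so the emulated cohort reproduces the reported band. Perfectly
coupled, low-noise recordings score > 0.9; independent channels score
< 0.15 (≈ 0.02–0.07 typically, matching the 0.05 ± 0.04 regime).

## The statistical protocol

`paired_compare()` applies a Shapiro–Wilk gate (α = 0.05) to the paired
differences: normal → paired t; otherwise the exact Wilcoxon
signed-rank test. `unpaired_compare()` gates both margins: both normal
→ Welch t; otherwise the two-sample Kolmogorov–Smirnov test (exact for
n₁·n₂ ≤ 10⁴). Significance is α = 0.05 throughout; no multiplicity
correction is applied, matching the emulated protocol.

The exact signed-rank p-value is computed by generating-function
convolution over the doubled mid-ranks — mathematically identical to
enumerating all 2ⁿ sign assignments, including tied ranks — for
n ≤ 25, with a continuity-corrected, tie-corrected normal approximation
above. Zero differences are dropped (classic convention) and counted.
The n = 10 all-same-sign case gives W = 0 and p = 2/1024 ≈ 0.00195,
printed as 0.002.

```{r wilcoxon}
wilcoxon_signed_rank_exact(-(1:10))[c("W", "p")]
```

## Tolerances and problem sizes

The package's consistency checks compare recovered statistics with the
reference values at three standard errors of the reference statistic at
its reported sample size (e.g. 1.07 ± 3·0.34/√100 s for the discharge
duration), since the reference values are themselves empirical means
with sampling error, while the simulated cohorts (200 slices) make the
recovered means essentially exact. Proportions (bursting fraction,
immediate-block fraction) use binomial standard errors at the simulated
cohort size.

Cohort analyses run at a 1 kHz sampling rate — the signal band is fully
below 100 Hz and the synchronization pipeline decimates to 1 kHz anyway
— with 10-minute slices; property-style tests use 300–600 s recordings
at 500 Hz with decimation disabled. The raw-acquisition default of
`simulate_recording()` remains 10 kHz.

## What passing tests do and do not show

The generator emulates the *statistical phenomenology* of each
condition: event shapes, rates, burst structure, coupling, block
latency, and the reported amplitude/frequency values. It does not model
biophysics — no membrane or receptor kinetics, no network dynamics, no
electrode artifacts, no non-stationarities beyond the block model.
Recovery of the encoded statistics therefore validates the *pipeline*
(detector conventions, the synchronization statistic, the statistical
protocol) and the internal consistency of the generator — it says
nothing new about the underlying biology, and performance on real
recordings will depend on how far their noise and waveform variability
depart from this model (in particular, real discharges vary in shape
far more than a single template family).

## Known limitations

* The detector's duration convention is co-designed with the template's
  reference level; on waveforms with a different decay law,
  half-threshold durations would be biased.
* The burst grouper assumes trains at ≥ 0.3 Hz; slower trains are
  (deliberately) not grouped.
* The exact KS branch inherits `stats::ks.test`'s tie handling
  (approximate p with ties, with a suppressed warning).
* `read_recording()` infers the sampling rate from the time column and
  requires strict uniform sampling.
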