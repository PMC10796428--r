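---
title: "Methods: signal processing for chemogenetic seizure-control experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing for chemogenetic seizure-control experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizr)
```

seizr implements the analysis stages of a chemogenetic epilepsy experiment
in which an engineered inhibitory acetylcholine-gated chloride channel is
used to suppress neuronal excitability and seizures in mice: Hill
dose-response pharmacology in cultured neurons, intrinsic excitability in
acute-slice patch-clamp recordings, electrically evoked seizure thresholds,
24/7 EEG seizure detection with drug-effect quantification, hippocampal
oscillation and sharp-wave-ripple analysis, and two-photon acetylcholine /
calcium trace analysis around seizures. Every stage is paired with a
synthetic-data generator that plants machine-readable ground truth, so the
whole pipeline is testable at desk scale without recorded animal data.

This vignette records the models, the parameter choices that were genuinely
open, and the known limits of what the synthetic tests demonstrate.

## Dose-response pharmacology

Per-cell drug-induced currents are the baseline-subtracted peak shifts in
holding current (`peak_drug_amplitude()`; the trace is lightly smoothed, 50
ms, before the extremum is taken, because the holding-current shift is slow
relative to sample noise whose extremes would otherwise bias a peak-picking
estimator upward). Amplitudes are normalized to the within-cell peak
response magnitude (`normalize_within_cell()`, maximum exactly 100), then
averaged across cells and fitted to the normalized Hill model

$$Y = \frac{100}{\left(1 + \mathrm{EC}_{50}/X\right)^{h}},$$

with $X$ the agonist concentration and $h$ the Hill slope
(`fit_hill()`). The fit runs in $\log_{10}\mathrm{EC}_{50}$ with a
multistart (EC50 grid at each observed concentration, slopes 0.5/1/2);
EC50 is bounded to the observed concentration range times $10^{\pm 2}$ and
$h$ to (0, 10].

One numerical subtlety drove a design choice: the within-cell peak used for
normalization is itself a noisy estimate of the true plateau. Selecting the
maximum of several noisy near-plateau responses overestimates the plateau,
which uniformly compresses the normalized curve; with a fixed top of 100
this inflates the fitted EC50 (about +12% at 5% response noise with 8
cells). `fit_hill()` therefore co-estimates the plateau scale as a nuisance
parameter (the standard three-parameter Hill fit) and reports parameters on
the normalized scale, so `predict(fit, ec50)` is exactly 50. This removed
the bias in simulation (median relative EC50 error 2.6% under 5% noise, 8
cells, 9 half-log doses) without changing the reported model. The
simulation conditions mirror the protocol: doses escalate in half-log steps
until the response plateaus, so recovery grids for a high-potency agonist
(EC50 ~0.02 uM) span 1e-3-10 uM and for a low-potency agonist (EC50 ~95 uM)
span 1-1e4 uM.

## Intrinsic excitability from current-clamp sweeps

The sweep protocol is a 500 ms rest, a -100 pA / 200 ms hyperpolarizing
step, a 300 ms gap, and a 2 s ramp from -150 to +500 pA, at 10 kHz.

* **AP detection** (`detect_aps()`): events are upstrokes with dV/dt above
  20 mV/ms sustained for two samples (the 3xSD rule below defines where a
  spike's threshold lies, not how events are found, so the event-detection
  level is a package choice). Each event's threshold is the voltage where dV/dt first
  exceeds 3x the SD of dV/dt over the quiescent pre-injection segment of
  the same sweep, walking back from the peak through the contiguous
  supra-level run.
* **AP width** (`ap_width()`): the spike is resampled to 100 kHz (spline
  interpolation; band-limited and linear interpolants agree to within one
  resampled sample here) and the width is the time above the half-height
  between threshold and peak. Cells with width <= 1 ms are putative
  fast-spiking interneurons; the classification boundary is exact at 1 ms.
* **Input resistance**: steady state is the mean of the last 25% of each
  hyperpolarizing step, referenced to the 100 ms before step onset; the
  step-series (culture) protocol averages its four hyperpolarizing steps.
* **Rheobase**: the command current at the first ramp AP; sweeps with no
  ramp APs are assigned exactly 500 pA. Spikes before ramp onset are
  flagged and excluded.
* **RMP**: the mean over the 500 ms immediately before any current
  injection; shorter pre-injection segments are an error, not a silent
  shorter mean.
* **QC**: cells are excluded when no APs occur in the initial sweep or
  when R_in exceeds 500 MOhm (configurable); individual sweeps are
  excluded when RMP exceeds -40 mV.
* **Drug time bins**: Baseline = [-60, 0) s, Drug = [60, 180) s, Wash =
  [480 s, end), half-open, with AP counts normalized per neuron to the
  Baseline mean; empty bins give missing values.
* **Culture firing**: per 90 s dose epoch, APs in a stable 60 s window are
  counted; "stable" is operationalized as the sub-window minimizing
  holding-current range when a holding trace is available, and the centred
  window otherwise.

The synthetic cell is a leaky integrate-and-fire neuron with a pasted 2 ms
AP waveform; its ground-truth rheobase is taken from the simulation itself
(the current at the first ramp crossing), i.e. already adjusted for ramp
kinetics, and approaches $(V_{thresh}-V_{rest})/R_m$ in the slow-ramp
limit. LIF dynamics lack adaptation, subthreshold resonance, and graded AP
amplitudes, so the tests exercise the estimators' arithmetic, not their
robustness to biological diversity.

## EEG seizure detection

The detector mirrors a semi-automatic interictal-spike-cluster pipeline:

1. zero-phase 4th-order Butterworth band-pass, default 1-50 Hz (the
   filter realization is a package choice);
2. candidate spikes where the absolute filtered signal exceeds
   `amp_thresh` (default 5) robust SDs — the SD is MAD-scaled over the
   whole filtered trace so the seizures themselves do not inflate it, and
   detection is therefore invariant to gain and DC offset;
3. per-candidate half-amplitude width and optional template
   cross-correlation (maximum over +/-5 ms lags), combined through a
   configurable Boolean expression (`"amplitude & width"` when no template
   bank is supplied);
4. artifact rejection by OR of a saturation rule (a sustained pinned run
   near the window extreme) and a broadband rule (excess >100 Hz power
   relative to the detection band);
5. greedy ISI clustering: gaps strictly below 1 s chain spikes, clusters
   closer than the inter-cluster interval (default also 1 s) merge, and
   clusters spanning strictly more than 3 s (alternative gate: 6 s) are
   seizures. The 6 s gate detects a subset of the 3 s detections by
   construction.

Numeric values for the amplitude threshold, width range, and template
correlation are experiment-specific tuning in this kind of semi-automatic
workflow; the defaults here (5 SD, 3-200 ms, 0.7) are package choices, all
configurable. Manual review edits are supported by operating on the
returned tables, not modeled algorithmically.

The synthetic LFP background is pink (1/f) Gaussian noise — realistic for
LFP, with white noise available. Planted seizures are 3 Hz spike-and-wave
(a mildly amplitude-modulated train of stereotyped epileptiform spikes
riding a phase-locked 3 Hz slow wave) plus a 35 Hz narrowband component,
at 8x / 4x / 4x the background SD. Planted amplitudes are expressed in
multiples of the background SD *within the relevant detection band* and
compensated for the waveform's in-band filter attenuation, so a planted
"8 SD" spike actually peaks near 8 detection-band SDs — the convention the
detector thresholds in. Under these conditions the detector attains
sensitivity 1.0 with zero false seizures over 20 seeded 630 s sessions at
1 kHz; isolated noise excursions cannot form a >3 s cluster, which is what
makes the false-seizure rate structurally zero rather than merely small.

## Evoked seizure thresholds

The stimulation schedule rises 10-100 uA in 10 uA steps, to 240 uA in 20
uA steps, then 30 uA steps, never exceeding 400 uA (the generated sequence
ends at 390 because a further step would exceed the 400 uA limit). A
post-stimulus response is an evoked seizure when the smoothed (0.5 s)
broadband amplitude envelope stays above the pre-stimulus baseline median
plus 3 robust SDs for at least 6 contiguous seconds, both the 2-4 Hz and
20-50 Hz band powers within that period exceed baseline by at least 4x,
and the elevation begins within 10 s of stimulation end. The envelope
factor (3) and band-power factor (4) operationalize qualitative criteria
and are configurable; the 1 s stimulus is blanked, not modeled. The
session threshold is the first schedule amplitude whose response
classifies as a seizure (censored if none by the end), and per-animal
shifts are drug/vehicle ratios after averaging replicate trials within
animal (differences available by flag).

## Oscillations and ripples

Active periods are detected from the 3-axis accelerometer as the smoothed
(0.25 s RMS) vector-norm motion magnitude, after 1 Hz high-pass gravity
removal, exceeding twice its median for strictly more than 5 s; gaps under
0.5 s are bridged. "Elevated" needs an estimator to be operational; a
noise-floor multiple of the magnitude median is used
because a MAD-based threshold degenerates after smoothing (the smoothed
magnitude's MAD is far below its median).

Band power uses an in-package multitaper estimator: DPSS tapers computed
from the standard Slepian tridiagonal eigenproblem (2 s windows,
time-bandwidth 3, 5 tapers, 50% overlap — conventional values, all
configurable), with anti-aliased decimation for heavily
oversampled traces. The estimator integrates a unit-amplitude in-band
sinusoid to 1/2 and is additive over band partitions. Theta (4-10 Hz),
low-gamma (20-55 Hz) and high-gamma (55-90 Hz) powers are measured only
during active periods, on the channel with greatest theta power.

Ripples are detected on immobility periods only: the 90-200 Hz filtered
trace's Hilbert envelope is smoothed (10 ms) and events seed where it
rises more than 5 robust filtered-trace SDs *beyond the envelope noise
floor* (its median), extending to the contiguous region more than 1 robust
envelope-SD above that floor. The floor subtraction matters: a noise
envelope has a Rayleigh floor of about 1.25 SD, so without it a planted
3-SD packet would reach ~5 SD in raw envelope units and the 5 SD seed rule
would not separate 3-SD from 8-SD events. The 1 SD extension could equally be defined on the raw filtered trace;
the envelope is used and documented as such. Events touching the first or
last 0.1 s are discarded (filter edge transients). Intra-ripple frequency
is the Welch PSD peak of the filtered event segment (single Hann segment
for short events, resolution 1/duration); mean amplitude is the average
Hilbert magnitude.

## Imaging traces

DF/F uses a time-dependent cubic baseline: the trace is smoothed with a 5 s
moving median; the first and last 5% of frames, running periods, and peaks
(iteratively, residuals above 2 SD of the current fit, three iterations)
are excluded; a third-degree polynomial fitted to the remaining samples is
$B(t)$ and $\mathrm{DF/F} = (F - B)/B$, which is invariant to
multiplicative gain. The smoothing window, edge fraction, peak rule and
iteration count are package choices; only the step sequence is fixed.

The event response is the post-window peak minus the 10 s pre-window mean;
a mean-mode variant (average signal change in the 10 s after onset) is
exposed because both definitions are in common use, with peak the default
for significance and mean available for correlation-style summaries. An event
is significant when its response strictly exceeds the 95th percentile of
responses at `n_random` (default 1000) uniformly random valid time points
of the same session; probes near true events are *not* excluded by
default, matching the literal procedure (a toggle exists). On event-free
synthetic sessions the criterion flags 5% of probes within binomial error.
Evoked responses compare the during-seizure peak with the mean of the 30 s
before stimulation. Seizure-aligned averages exclude truncated events and
report per-timepoint SEM, and the ACh-calcium relationship is ordinary
least squares with Pearson r and a 95% confidence band.

The imaging generator plants exponential-decay transients (3 s decay) in
DF/F units on a positive cubic drift, with ACh amplitudes equal to calcium
amplitudes times a coupling factor; it emulates neither motion artifacts
nor out-of-focus background, so DF/F tests certify baseline and response
arithmetic, not robustness to real imaging noise.

## Treatment effects on seizure timelines

Seizure logs are binned into 30 min half-open bins aligned to injection,
and each animal's per-bin frequency and mean duration are normalized to the
first 30 min bin starting one hour before injection, [-60, -30) min (a
sensitivity option normalizes to the [-60, 0) mean instead). Zero-seizure
bins yield missing durations, not zeros, and empty reference bins flag the
animal rather than silently producing infinities. Duration normalization uses the per-bin mean by default; the tables make
a median variant a one-line change.

For cohort-level effect estimation the package pools counts across animals
(ratio of total post-injection to total reference-window rate,
`estimate_rate_multiplier()`): the per-animal frequency ratio that the
display normalization produces is Jensen-biased upward at finite reference
counts (about +11% at a reference mean of 10 events), while the pooled
ratio is unbiased to O(1/total-count). Both views are exposed; simulations
use the pooled estimator for recovery checks and keep the per-animal
normalization as the display quantity.

Synthetic timelines are nonhomogeneous Poisson processes generated by
thinning, with lognormal event durations (meanlog = log 20 s, sdlog = 0.5,
typical of chronic hippocampal electrographic seizures) and a baseline
rate default of 20 events/h, in the range reported for
intrahippocampal-kainate electrographic seizures; the drug effect is a
step rate-multiplier for a configurable window after injection. Per-bin
paired comparisons use the standard paired t-test with optional
multiple-comparison adjustment; mixed-model analyses of cumulative counts
are left to standard routines (e.g. `nlme`/`lme4`) on the tidy tables this
package produces, since that machinery is not this pipeline's
contribution.

## Problem sizes used by the test suite

The default suite and the acceptance script run at desk scale, sizes
chosen to make the Monte Carlo checks decisive: 20 x 630 s EEG sessions at
1 kHz (10 planted seizures each), 20 x 100 s ripple sessions at 2 kHz, 50
event-free imaging sessions of 600 s at 15 fps with 500-probe nulls, 500
six-hour seizure timelines, 100 dose-response refits, and 99 simulated
sweeps for the R_in bias check. Sampling rates of 1-2 kHz are used for
LFP synthesis (the acquisition hardware's 5 kHz adds nothing for bands
below 200 Hz); all estimators accept any rate above the relevant Nyquist
requirement.

## Known limitations

* Ground-truth-planting generators share waveform families with the
  detectors' assumptions; passing tests demonstrate correct implementation
  of the stated rules, not detector performance on real EEG, which
  contains artifact classes and seizure morphologies the generator does
  not emulate.
* ROI segmentation and motion correction are out of scope; masks and
  traces are inputs.
* The semi-automatic detector's manual-review stage is supported only as
  table edits, not modeled.
* Animal-level inferential statistics (ANOVAs, mixed models) are thin
  calls to standard routines on the package's tidy outputs, not
  reimplemented here.
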