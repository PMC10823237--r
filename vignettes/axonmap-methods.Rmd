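---
title: "Methods: detecting thalamocortical axons and inferring monosynaptic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting thalamocortical axons and inferring monosynaptic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmap)
```

## The problem

A high-density silicon probe inserted tangentially through layer 4 of
mouse primary visual cortex (V1) records two kinds of extracellular
signal at once: the compact biphasic action potentials of cortical
somata (V1N) and much smaller, multipeaked waveforms left by
thalamocortical axons (TCA) arborizing in the same tissue.  Because
presynaptic axons and postsynaptic neurons are sampled by one electrode,
spike-train cross-correlation can map monosynaptic thalamocortical
connectivity at a scale unreachable with paired dual-region recordings.
`axonmap` implements that analysis chain -- waveform extraction and
axon/soma classification, jitter-corrected cross-correlogram (CCG)
connection detection, spike transmission efficacy, conduction-speed
estimation, spike-triggered axonal footprints, receptive-field and
trial-variability summaries -- together with a ground-truth simulator
that makes every stage testable on a desk.

## Multichannel waveforms

The multichannel waveform (MCW) of a unit is the mean spike-band snippet
over a `[-5, +5]` ms peri-spike window across all channels, averaged over
up to 50,000 spikes (a seed-deterministic subsample beyond that).  The
window is wider than the usual +/-2 ms because the propagation analysis
needs a `[-5, -2.5]` ms noise baseline.  Before averaging is interpreted,
each channel is advanced by `adcRank x 2.78` us: channels of one
analog-to-digital converter are digitized sequentially, and at 30 kHz
that stagger (a twelfth of a sample) matters for sub-millisecond peak
timing.  The shift is sub-sample, so it is applied by band-limited (FFT
phase) interpolation rather than sample moves.  The simulator applies
the same stagger with the opposite sign when rendering, so
render-then-correct is an identity up to interpolation error; this
direction convention is internal -- the testable contract is the
roundtrip.

Per-channel amplitude is summarized by a normalized profile: the
peak-to-peak excursion of the mean MCW per channel, divided by its
maximum over channels.  The *spread* is the number of channels above 0.1
of that profile, and its vertical extent in um (one row pitch is added so
a single supra-threshold row reports 20 um rather than 0).  The phrase
this quantifies -- variability of the per-channel maximal amplitude --
admits more than one reading; peak-to-peak of the mean waveform is the
one used here, chosen because it is noise-robust at realistic spike
counts and reduces to the obvious answer on noise-free templates.

## Axon versus soma classification

A unit is classified TCA when its waveform carries a second, late
rebound peak longer than 1 ms (measured at half the rebound height;
the duration rule is a package choice since only the ">1 ms" criterion
is stated) that spreads over more than 10 channels.  The rebound spread
is measured on the rebound's own time window -- from the zero crossing
after the trough onward -- because that window isolates the axon's
dendritic/synaptic contact field (DF) from the early axonal field (AF);
applying the spread criterion to the full waveform would mix the two.
Units failing the axon rule with a clear trough (|trough| >= 10 uV by
default) are V1N; the rest stay unclassified.  AF and DF are separated
at the zero crossing between trough and rebound at the peak channel,
and amplitude/spread metrics are computed per segment.

## Conduction speed

When the probe happens to lie along an axonal path, the spike arrives at
successive channels of one electrode column with a fixed delay per
micrometre.  Per column, an AP peak time is assigned to each usable
channel (at least 5 in-column channels away from the peak channel's row
and 5 from the tip) whose amplitude within `[-2.5, -0.1]` ms exceeds 4
SDs of its own `[-5, -2.5]` ms baseline; peaks landing exactly on the
window edge are rejected as clipped.  The peak time is the time of the
largest |amplitude| rather than the first threshold crossing: on
noise-free or well-averaged waveforms the two coincide, but the
crossing time degenerates when the baseline SD approaches zero.  A line
fitted to time versus vertical position must reach |R| > 0.725; the
best-correlated column's slope gives the speed in m/s.  Simultaneous
peaks (zero slope) and noise-dominated fits return no estimate.

## Jitter-corrected CCGs and connection detection

The CCG counts postsynaptic-minus-presynaptic spike-time differences in
half-open 0.1 ms bins over +/-10 ms.  The bin width is a package choice:
the detection rule's "at least 4 consecutive bins" inside a 3.5 ms
window implies sub-millisecond bins, and 0.1 ms makes the minimum peak
width 0.4 ms, matching sharp monosynaptic peaks.  Slow co-modulation
(shared rate fluctuations, oscillations) is removed by jitter
correction: every postsynaptic spike is re-drawn uniformly inside its
fixed 10 ms wall-clock window (window k is `[10k, 10k+10)` ms), the CCG
of 50 such surrogates is averaged, and the surrogate mean is subtracted.
Only the postsynaptic train is jittered -- equivalent in expectation and
half the cost.  The baseline SD of the corrected CCG is measured over
`[-4.5, +0.5]` ms (on the corrected, not the raw, correlogram -- the
corrected baseline is the noise that a candidate peak must beat).

A connection is declared when at least 4 consecutive bins inside the
monosynaptic lag window `[0.5, 4]` ms exceed 3 baseline SDs.  Only
positive lags are tested: the direction is thalamus to cortex.

## Spike transmission efficacy

Efficacy is the area under the corrected monosynaptic peak divided by
the presynaptic spike count: the probability that a thalamic spike adds
a cortical spike.  The integration window is the significant run
extended outward while adjacent bins stay above 1 SD.  One correction is
applied to the plain area: the jitter surrogates redistribute each
evoked coincidence across the 10 ms jitter window, so the corrected
area under-counts the peak by the factor `1 - W/J` (W = integration
window width, J = jitter window).  Because every evoked spike's
surrogate interval covers the peak lag, dividing by `1 - W/J` (with
W/J capped at 0.5) removes this bias exactly in expectation.  Without
the rescaling the estimator runs ~10-15% low at synaptic jitter of
0.1-0.3 ms, which is visible against ground truth; with it, planted
transmission probabilities from 0.01 to 0.5 are recovered with a few
percent relative error at 20,000+ presynaptic spikes.

## STA footprints on a second probe

For dual-probe configurations, the spike-triggered average (STA) of the
postsynaptic probe's spike band at presynaptic spike times reveals the
axon's synaptic footprint.  Presynaptic triggers within +/-1 ms of any
postsynaptic spike are removed first (otherwise postsynaptic somatic
spikes, time-locked through the connection, leak into the average), and
at most 20,000 of the remainder are used.  The footprint is read at the
postsynaptic neuron's peak channel and at the CCG peak lag minus 1 ms
(rounded to the nearest sample; the amplitude is taken at that exact
lag, not minimized over a window).  Width is the number of channels
below -0.75 uV at that lag; width 0 is reported as not detected.  The
threshold follows the stated rule (interpreting the printed "-075 uV"
as -0.75 uV, consistent with footprint amplitudes near -1 uV).

## Visual characterization

Receptive fields from sparse noise: spikes inside each 100 ms frame are
accumulated on the frame's pixel over repeats (36 x 22 grid by default,
full-frame evoked window with an optional latency shift).  The map is
cubic-spline interpolated to twice the resolution on both axes, and its
signal-to-noise ratio is `1/SD` of the peak-normalized map (the
normalization is a declared choice; the screen passes maps with SNR
above 15).  Note the screen is calibrated for the full grid: on small
toy grids a perfect single-pixel RF cannot exceed the threshold because
the SD of a one-hot map is fixed by the pixel count.  Trial variability
is the Fano factor, unbiased variance over mean of per-trial spike
counts; thalamic relay cells run sub-Poisson (about 0.7) and cortical
neurons super-Poisson (about 1.1) under repeated stimulation.

## The simulator

Ground truth comes from `simulateTrains()`, `makeTemplate()` and
`renderRecording()`:

* Spike trains are homogeneous Poisson processes thinned by an absolute
  refractory period (2 ms default).  A connection gives each presynaptic
  spike an independent chance `p` of adding one postsynaptic spike at
  `delay + N(0, jitter)`; evoked spikes are never suppressed, so
  expected efficacy equals `p` exactly, and each transmission is flagged
  in the returned ground truth.  An evoked spike does suppress baseline
  postsynaptic spikes inside its refractory period: without that, evoked
  baseline collisions give connected units ISI-violation rates well
  above the 0.05% quality screen, and the screen would reject exactly
  the units carrying the planted connections.  Thalamic burst/tonic
  structure is not modeled; trains are Poisson-with-refractoriness and
  results on real bursty trains may differ.
* Somatic templates are a narrow negative Gaussian trough plus a small
  positive overshoot well under 1 ms, so somata can never satisfy the
  rebound criterion.  Axonal templates are an AF (trough, damped
  overshoot, small undershoot so the trace re-crosses zero before the
  rebound) plus a DF rebound whose half-height duration and spatial
  spread are set directly; the AF overshoot is rendered at 0.3 of the
  nominal positive amplitude so the late DF rebound is the largest
  post-trough excursion, as in recorded axon waveforms.  Spatial decay
  is Gaussian in distance with the scale calibrated so that *exactly*
  the requested number of channels exceeds 0.1 of the profile
  (distance ties broken by an index epsilon).  Default amplitudes are
  the reported population means (soma -54.9/+24.6 uV; AF -26.1/+12.8;
  DF -12.5/+12.1), placing fixtures in the realistic regime.  A finite
  conduction speed adds a propagating spikelet along the peak channel's
  column toward the tip.
* Rendering superposes templates at spike times (linear by
  construction), applies the per-ADC stagger by band-limited
  resampling, and adds i.i.d. Gaussian noise.  Values stay in uV;
  quantization to int16 happens when writing the flat-binary file.
  Electrode drift, overlapping-spike sorting errors and biophysical
  volume conduction are not modeled -- passing tests show the analysis
  chain is correct on its own assumptions, not that those assumptions
  hold in tissue.

## Numerical choices and degenerate inputs

* Peak-channel ties go to the lowest channel index.
* CCG bins are half-open `[lo, hi)`; the identity
  `corrected + jitterMean = raw` holds exactly.
* An empty presynaptic train yields an all-zero CCG with a warning; a
  zero-baseline-SD corrected CCG refuses detection with a diagnostic.
* The isolation-distance covariance is ridge-regularized
  (`1e-6 x trace/dims`) and flagged when singular.
* QC boundaries are strict as printed: ISI violations strictly above
  0.05% fail; isolation distance must be strictly above 10 to pass.
  The refractory window (1.5 ms) and double-count window (0.2 ms) are
  unstated upstream and exposed as configuration.
* Every stochastic step takes a seed; the pipeline derives per-stage
  seeds by hashing the stage name into the master seed, so adding a
  stage never changes another stage's stream.

## Problem sizes used in validation

The test-suite and acceptance analyses run at desk scale, chosen to
keep each statistical check well-powered: efficacy recovery at 15 Hz
presynaptic rate for 1,400 s (>= 20,000 presynaptic spikes, 2-5 seeds
per transmission probability), false-positive calibration on 500
independent 1,800 s Poisson pairs at 10-20 Hz, classification banks of
40 noise-free and 20 noisy units (2,000 spikes each, 10 uV noise, 32
channels), conduction speed and STA discrimination over 10 and 20 seeds
(5,000 STA triggers; at 10 uV noise the trigger average leaves 0.14 uV
of residual noise, far from both decision margins), and 10,000 trials
for the Fano calibration.  In-vivo population statistics (amplitude
distributions, median efficacy, median pair distance) depend on the
recorded tissue and are not reproduced by simulation; the printed-count
arithmetic (detection probability, per-recording means) is reproduced
exactly.

## Known limitations

Inhibitory (trough) connections are not detected; CCG contamination by
sorting errors is not corrected; the generator's visual responses are
rate-based (no adaptation or bursting); dual-probe clock alignment is
assumed done.  The classifier replaces the original manual curation
step with the deterministic rebound rule plus an override column --
on real data borderline units still deserve eyes.
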