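---
title: "Methods: laminar analysis of developing barrel cortex recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar analysis of developing barrel cortex recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lamindev` implements the analysis chain used for multi-electrode in vivo
recordings from the developing mouse somatosensory barrel field (S1BF):
current-source density (CSD) based layer assignment, characterization of
spontaneous spindle bursts, sensory-evoked LFP/MUA response metrics with
paired-pulse adaptation, and PCA + k-means developmental staging. This
vignette documents the models, the parameters that matter, the numerical
choices behind them, and what the built-in synthetic recordings do and do
not demonstrate.

## Data model

A `recording` holds a channels-by-samples LFP matrix in millivolts, one
spike-time list per channel (spike sorting is upstream and out of scope),
contact depths in micrometers increasing with channel index, and the
vertical contact spacing *h* (default 50 µm, a standard single-shank
polytrode pitch). Stimulus tables list deflection onsets with a speed label
(5, 10, 20, 40, 80 Hz width-equivalents of a rectified sine), an
inter-stimulus interval (ISI) label for paired-pulse trials (0.10, 0.25,
0.50, 1.00, 1.50 s), and a block id; blocks hold 20 trials with a 30 s
inter-trial interval.

On disk a recording is a small directory: `meta.json` plus raw
little-endian float64 payloads for the LFP and spike times. Binary payloads
make the write/read round trip bit-exact, which decimal rendering of
doubles cannot guarantee.

## Channel quality control

Line-contaminated contacts are identified from the Welch power spectrum
(4 s non-overlapping Hamming-windowed segments, the same convention used
for all spectra in the package). For each channel the log-power at 50 Hz is
compared to a running-median spectral trend (5 Hz-wide neighborhood, the
49-51 Hz notch excluded) and standardized by the SD of the residuals over
20-80 Hz (notch excluded). A channel is kept when this 50 Hz excess score
is below 2 SD and the channel shows nonzero variance. The frequency band
over which the residual SD is taken is configurable; 20-80 Hz brackets the
line frequency while avoiding the steep low-frequency shoulder of the
1/f spectrum.

After layer assignment, `equalize_layer_counts()` retains the same number
of contacts in the supragranular (SG), granular (G) and infragranular (IG)
groups — the minimum across layers — so that layer comparisons are not
biased by contact counts. Surplus channels are dropped deterministically:
farthest from the granular sink-center channel first, ties resolved toward
the smaller channel index.

## Current-source density and layer assignment

The CSD at depth *z* is the negative second spatial difference of the
potential profile,

$$C(z) = -\frac{\Phi(z+h) - 2\Phi(z) + \Phi(z-h)}{h^2},$$

so that current sinks are negative. Extracellular conductivity is not
modeled; CSD values are in mV/µm² up to that constant, and only relative
sink structure is interpreted. Three options mirror common laminar
practice:

* **Vaknin correction** — the profile is padded by duplicating the topmost
  and bottommost contacts so the estimate is defined at the boundary
  channels and the output keeps the input channel count. Note a boundary
  estimate under end-duplication is not curvature-free for linearly varying
  profiles: the affine-profile-gives-zero identity holds exactly at all
  channels only without padding, and at all interior channels with it.
* **Pair averaging** — vertically adjacent contacts are averaged before
  differencing (collapsing a staggered two-column probe to one depth
  column); the effective spacing doubles.
* **Hamming smoothing** — each depth profile is smoothed with the
  three-point kernel (0.23, 0.54, 0.23) before differencing, boundary
  values duplicated. The order of operations is pair-average, Vaknin pad,
  smooth, difference.

Layers are assigned on the stimulus-aligned, trial-averaged CSD: among
channels whose post-stimulus sink exceeds half of the largest sink
magnitude on the map (configurable `amplitude_fraction`), the channel with
the earliest sink-peak latency seeds the granular group; contiguous
neighbors that also meet the amplitude criterion within a 10 ms latency
tolerance extend it. Channels above are SG, below are IG. The default
search window is 0-100 ms post-stimulus (the pipeline widens it to 150 ms
to accommodate the slow latencies of the youngest ages).

## Spontaneous activity

**Spectra.** `welch_band_power()` normalizes the Welch PSD by its
trapezoidal area so spectra are comparable across animals; band powers are
the mean normalized density over alpha-theta (5-15 Hz), beta (15-30 Hz) and
gamma (30-50 Hz).

**Spindle-burst detection.** The signal (by default the average of the
retained granular-layer contacts; a per-channel mode exists) is band-passed
5-35 Hz with a 4th-order Butterworth filter applied forward and backward —
zero phase preserves onset timing, and the effective magnitude order
doubles. The instantaneous envelope is the modulus of the analytic signal.
Detection is two-stage:

1. *Core detection and screening.* Maximal intervals where the envelope
   exceeds mean + 2 SD (both over the whole record) are putative events;
   the threshold is applied to the envelope, which is the reading under
   which the Hilbert step has a purpose (an SD-of-filtered-trace variant is
   available). Putative events closer than 50 ms are merged so envelope
   flicker cannot split one burst. Events shorter than 100 ms or with fewer
   than 3 troughs are discarded. Screening happens at this stage, on the
   supra-threshold interval itself, so brief noise crossings can never
   survive by borrowing duration from the extension below.
2. *Boundary extension.* Because an oscillatory burst waxes and wanes, the
   supra-threshold crest underestimates the event: surviving events are
   extended outward to where the envelope falls below a noise-floor edge
   (median + `edge_sd` robust SDs of the envelope; default the median
   itself) and on to the local minimum of a 50 ms boxcar-smoothed envelope.
   Robust statistics are essential for the edge: the events themselves
   inflate a mean/SD-based level. Overlapping extensions collapse to one
   event.

Troughs are strict local minima of the filtered trace with negative value
(plateaus count once, at their first sample). In the reported counts a
trough must additionally sit where the envelope clears the edge level and
dip below its negative, so shallow noise dips in the low-amplitude fringe
of an event are not mistaken for oscillation cycles. The intra-event
frequency is troughs / duration — by construction exactly the ratio of the
two reported fields. For a single short event this estimator is coarse
(one trough more or less moves a 0.3 s event by ~3 Hz); it is unbiased in
the mean over events, which is how it should be consumed.

**Spectrograms and firing rate.** Event-aligned spectrograms use a complex
Morlet continuous wavelet transform (centre parameter 6, 48 log-spaced
frequencies covering 5-50 Hz), averaged across event-onset-aligned
segments; events whose window does not fit the record are skipped with a
warning. The baseline firing rate averages spike counts over non-overlapping
500 ms windows (hop configurable), which equals count/duration when the
windows tile the record.

## Evoked responses

Evoked LFP responses are trial-aligned averages with the mean of the 100 ms
pre-stimulus baseline subtracted per trial. PSTHs count spikes in 1 ms bins
summed across trials, convert to spikes/s per trial (counts / (trials ×
bin)), smooth with a zero-padded 5 ms boxcar (zero-padding conserves the
total count; the smoothing width must be an odd multiple of the bin so the
kernel is centred), and subtract the mean of the pre-stimulus bins after
smoothing. Peaks are the most negative LFP deflection or the maximum MUA
rate within 0-100 ms post-onset (configurable); latency runs from
deflection onset to the extremum, ties resolving to the earliest sample,
and flat responses are flagged degenerate rather than given a latency.

The paired-pulse ratio divides the second response's peak amplitude by the
first's, each measured against its own pre-onset baseline. At short ISIs a
100 ms second baseline would reach back into the first response's decay, so
it is shortened to at most 40% of the ISI — at the protocol's shortest ISI
(0.1 s) that is a 40 ms window ending at the second deflection, clear of a
first response peaking ~30 ms after its onset. The second response is
flagged a failure when its peak does not exceed twice the SD of the first
pre-stimulus baseline; this max-versus-SD comparison is meaningful for
band-limited trial-averaged traces (for broadband per-sample noise the
maximum of a 100-sample window exceeds 2 SD almost surely). A first peak
below that same floor makes the ratio undefined and raises an error.

Condition aggregates collapse each subject to its own mean first, then
report mean ± SEM with N = subjects per (genotype, age window, layer,
condition) cell, matching the convention that N counts animals, not trials.

## Developmental staging

The feature matrix concatenates, per subject, the averaged evoked LFP and
the MUA PSTH over −10 to +100 ms at 1 kHz — 110 + 110 = 220 features, LFP
block first. The LFP is linearly resampled onto the 1 kHz grid; the PSTH is
bin-mean down-sampled (identity when its bins are already 1 ms). Columns
are z-scored by default: the two blocks mix millivolts and spikes/s, and
without scaling the larger-variance modality dominates the PCA. An
unscaled mode is available for fidelity runs; neither mode is asserted to
be what any particular laboratory used.

PCA retains the smaller of the number of components reaching 75% cumulative
explained variance and 10 components. k-means (50 restarts per k, best
inertia kept, Euclidean metric) is scanned over k = 2..10; the mean
silhouette width over subjects selects k, ties resolving to the smaller k,
and values of k ≥ N are skipped with a warning. A winning silhouette below
0.4 sets a `weak_structure` flag, since the scan's argmax convention
returns k = 2 even for a single isotropic cloud. The scan seed is an
explicit argument, and a fixed seed reproduces labels exactly.

## The synthetic-recording generator

`generate_recording()` builds laminar recordings with complete ground
truth. Its defaults are the experimental protocol itself: blocks of 20
trials, 30 s inter-trial intervals, the five deflection speeds with
amplitude increasing (0.20-0.90 mV at the sink centre) and latency
decreasing (80-30 ms) with speed, paired-pulse blocks at the five ISIs with
a CP-like "reverse-U" prescribed-PPR profile peaking at 0.5 s, spindle
bursts at 6/min with 8-25 Hz carriers and 0.3-1.5 s durations over 1/f
noise (SD 0.1 mV; burst amplitude 0.5 mV), and optional pure 50 Hz
contamination on designated bad channels. These amplitudes, latencies and
rates are in the range reported for neonatal rodent barrel cortex; they are
fixed here once and the tests never move them.

The evoked response is a zero-sum laminar dipole: a Gaussian sink profile
(half-width one channel) normalized to −1 at the granular centre, flanked
by half-amplitude sources rescaled so the spatial sum is exactly zero —
which makes CSD sink localization exact and charge conservation testable.
Its temporal kernel is a Gaussian whose support starts exactly at the
deflection onset, so pre-stimulus baselines of noise-free recordings are
exactly zero and peak recovery can be asserted with zero error. Bursts are
Hann-windowed constant-frequency carriers, making the expected trough count
unambiguous. Spikes are thinned from a homogeneous Poisson majorant: the
rate is elevated multiplicatively during bursts and by a Gaussian bump
after each deflection, the second pulse scaled by the prescribed PPR.
Paired-pulse trial periods are ITI + ISI so trials cannot collide at long
ISIs. `generate_cohort()` draws per-subject seeds deterministically from a
base seed; `age_group_profiles()` provides CP-like (small/slow, burst-rich),
pre-AW and AW-like (large/fast, burst-poor) parameter sets.

What the generator does *not* emulate: spike waveforms (sorting is out of
scope), conductance-based biophysics, moving or oblique probes, non-Hann
burst envelopes or within-burst frequency drift, cross-channel correlated
noise, and electrode drift. Detection and recovery results on synthetic
data therefore demonstrate the pipeline's correctness under its stated
model, not field performance on arbitrary recordings — in particular, a
Hann flank buries a burst's first ~10% below the noise floor, which is why
onset accuracy is assessed with a ±100 ms matching window.

## Numerical and design choices

* The laminar CSD uses the standard second-difference estimator with sinks
  negative; a transcription that subtracts (rather than adds) the
  lower-neighbor potential is not a curvature operator and is not
  reproduced.
* Welch PSD, analytic-signal envelope and Morlet CWT are implemented on the
  FFT directly; Butterworth design/zero-phase filtering come from the
  `signal` package, PCA/k-means from `stats`, silhouettes from `cluster`.
* The detector is exactly invariant to DC offsets because the signal is
  demeaned before filtering.
* The pipeline writes CSV/JSON with fixed formatting, and a rerun with the
  same configuration and seed is byte-identical; the manifest records the
  package version, a hash of the scientific configuration (output paths
  excluded) and the seed.
* Age windows default to CP = P5-8, pre-AW = P9-11, AW = P12-16 and are
  configurable.
* Test and acceptance problem sizes are deliberately desk-scale — 8-16
  channels, 25-60 s baselines, 4-5 trials per block for localization tests
  and the protocol's 20 trials per block where trial-count matters (the
  paired-pulse benchmark) — sizes at which every property above is
  measurable in seconds while the scientific parameters stay at their
  defaults.

## Known limitations

* The granular/SG/IG partition assumes a single dominant early sink;
  recordings with multiple comparable sinks (or none) raise errors rather
  than guessing.
* Trough-count frequency estimates are coarse for single short events.
* Paired-pulse peaks at ISI shorter than the response latency + width
  overlap the preceding response; the shortened second baseline mitigates
  but cannot eliminate this, which is one reason failures dominate the
  shortest ISI at young ages.
* The PPR estimate from a 20-trial average carries irreducible noise of
  roughly 0.02 SD at the generator's default signal-to-noise ratio;
  per-condition means across animals are the intended unit of analysis.
* No inferential statistics are produced; the output tables are descriptive
  and are intended to feed whatever testing framework a study prescribes.
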