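---
title: "Extracting and quantifying fictive swim episodes from dual ventral-root recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and quantifying fictive swim episodes from dual ventral-root recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fictiveswim)
```

## The problem

A paralyzed zebrafish larva still "swims": its spinal locomotor network
produces rhythmic motor-neuron output that would, in a free animal, drive
alternating left-right tail beats at 15-60 Hz. Recording this *fictive
locomotion* with a pair of extracellular electrodes on contralateral
hemi-segments gives a two-channel voltage series in which swim bouts appear
as episodes of spike bursts riding on noise: bursts alternate between the
two sides at the tail-beat frequency, bouts last roughly 0.1-2 s, and the
tail-beat frequency within a bout rises, falls, stays flat, or rises and
then falls. A biologically important landmark is 30 Hz: slow and fast swims
are driven by distinct motor-neuron pools ("speed modules"), and bouts that
cross 30 Hz capture the switch between them.

`fictiveswim` implements a complete, seeded, testable pipeline for such
recordings: wavelet denoising, unbiased episode extraction, burst
segmentation, left-right coordination scores, activity traces, instantaneous
tail-beat frequency, circular phase/coherence statistics, bout
classification, and alignment of somatic calcium imaging to the
electrophysiology. Because raw recordings of this kind are rarely deposited,
the package also contains a generator of synthetic recordings with full
ground-truth annotation; every stage of the pipeline is validated against
what the generator injected.

## The synthetic generator: what it emulates, and what it does not

`generate_recording()` builds each bout from an injected instantaneous
frequency trajectory $f(t)$. Left-channel bursts start where the
accumulated phase $\int f\,dt$ crosses integers; right-channel bursts are
offset by `phase_deg`/360 of a cycle (180° = anti-phase alternation).
Each burst occupies `burst_duty` (default 30%) of the cycle and is a train
of biphasic difference-of-Gaussians spike waveforms of ~1 ms total width,
with per-burst lognormal amplitude (SD 0.15 on the log scale) and additive
white Gaussian noise (optional 1/f component). Design choices worth
spelling out:

* **Within-burst spike spacing.** Spikes are laid at ~4 ms intervals across
  the burst (2-7 spikes depending on the tail-beat period) rather than a
  fixed count. A fixed 2-spike burst at low tail-beat frequencies would
  have a within-burst inter-spike interval larger than the 8 ms gap that
  defines burst boundaries downstream, which would make the annotation
  internally inconsistent.
* **Spike waveform asymmetry.** The negative lobe is 0.55 of the positive
  lobe. With near-equal lobes, noise can make the rectified negative lobe
  the locally largest extremum, which misstates spike timing by the lobe
  separation through no fault of the detector.
* **Trajectory identifiability.** Sloped and rise-fall bouts get a duration
  floor of 0.5 s and a frequency excursion of at least 12 Hz (scaled up for
  long bouts so the trend slope stays well above the 5 Hz/s
  continuous-versus-sloped decision threshold). A 150 ms bout spanning 3 Hz
  simply does not contain the information needed to call it "increasing",
  and generating unidentifiable examples would only measure label noise.
* **Presets.** The four stimulation presets are *qualitative* calibrations:
  `spontaneous` centres bout frequency near 24 Hz; `nmda` near 16 Hz
  (median below 20 Hz), with mostly flat trajectories; `electrical`
  produces short decelerating bouts starting above 30 Hz; `optomotor`
  draws bout frequency from an equal mixture of normals at 26 and 34 Hz,
  straddling the 30 Hz boundary. The constants live in one table,
  `preset_defaults()`. They reproduce orderings and shapes (which preset
  crosses 30 Hz more, which is slower), not any empirical histogram.
* **Artefact injectors** mirror the recognized failure modes of evoked
  fictive swimming: `stim_artefact` (a large decaying transient saturating
  both channels at stimulus onset), `dual_frequency` (the two sides driven
  >8 Hz apart), `incoherent` (Poisson spiking with no burst rhythm), and
  `erratic_burst` (an abrupt mid-bout switch from low-amplitude irregular
  spiking to fast high-amplitude bursting).

What the generator does **not** emulate: electrode drift, line noise,
movement of the preparation, bursts with internal amplitude structure,
correlated (common-mode) noise across channels, or multi-unit waveform
diversity. Tests passing on synthetic data therefore demonstrate that the
algorithms recover what they are defined to recover under controlled
conditions — not that any particular laboratory recording will be this
clean. The free parameters a real recording would pin down (amplitude
units, signal-to-noise ratio, within-burst spike rate) are exposed as
configuration rather than asserted.

## Wavelet denoising

Raw traces are denoised with an analytic Morlet continuous wavelet
transform ($\omega_0 = 6$, Torrence-Compo normalization) over log-spaced
scales covering 50 Hz to one quarter of the sampling rate (16 voices per
octave), hard thresholding of coefficient magnitudes, and single-integral
(delta) reconstruction. The reconstruction constant is computed in closed
form as the in-band gain of $\sum_j \mathrm{Re}\,W_j/\sqrt{s_j}$ for a
mid-band sinusoid; with this scale density the gain is flat across the band
and inversion is accurate to well under 1% (verified against closed-form
coefficient profiles in the tests). Edges are handled by reflection padding
of one full wavelet support. With the chosen normalization, white noise has
flat expected coefficient power across scales, so a single noise estimate —
the MAD of the finest-scale coefficients — sets the threshold everywhere.

The threshold rule deserves explanation. The classical universal threshold
$\sigma\sqrt{2\ln N}$ is about $4.6\sigma$ at these record lengths, while a
one-cycle biphasic transient has essentially *no* matched-filter gain under
a six-cycle Morlet: the peak coefficient of a unit spike is about 0.85
amplitude units. The universal rule therefore erases every spike below
roughly five noise SDs — precisely the low-amplitude units a denoising
front-end exists to preserve — and in our measurements it made the
conventional band-pass *better* at recovering low-SNR spikes. The default
is therefore `threshold_rule = "sd_multiple"` with $k = 3.5$, a
conventional spike-preservation operating point; `"universal"` remains
available. At the default, seeded white noise is suppressed to ~5% of its
input RMS, noiseless traces are denoised nearly idempotently (<1% RMS
change), and at spike amplitudes of 2.5 noise SDs the wavelet route
recovers roughly twice as many ground-truth spikes as the 100-1000 Hz
zero-phase Butterworth baseline under the identical detector.

Timing preservation is stated carefully: for ≥95% of ground-truth spikes
(at noise 0.25 of spike amplitude) a local maximum of the denoised
rectified trace lies within ±0.2 ms of the true spike time. A spike whose
amplitude falls below the coefficient threshold is removed entirely — that
is what denoising means — so the timing property is about *not moving*
peaks, while *how many* survive is the denoising-superiority comparison.

## Episode extraction and penalty scores

Peak detection takes local maxima of the rectified denoised trace above
`peak_min_amplitude` (default 4) noise SDs, at least 1 ms apart. On a
denoised trace most baseline samples are exactly zero, so the noise SD is
the Gaussian-consistent MAD of the *nonzero* samples, with a floor of 2% of
the trace maximum to reject reconstruction ringing on noise-free input. The
surviving-excursion distribution is heavier-tailed than Gaussian; over long
fully quiescent stretches occasional excursion clusters can pass, which the
100 ms rule almost always removes — a rare survivor shows up with a low
burst count and near-zero coherence. We deliberately did not raise the
threshold to eliminate these entirely: calibrations that did so also pushed
the threshold above the median surviving low-SNR spike and inverted the
wavelet-versus-band-pass comparison, sacrificing the method's point for
cosmetics.

Episodes are single-linkage clusters of the pooled (left+right) spike
times, split at gaps above 100 ms; clusters spanning less than 100 ms are
dropped and counted, never emitted. Within an episode, per channel,
consecutive spikes at most 8 ms apart form a burst; a one-spike burst has
duration zero and undefined within-burst frequency but still counts as a
burst. Burst ordering across channels breaks ties left-first for
reproducibility.

Two scores quantify left-right coordination, both in [0, 1]:

* **Alternation penalty** — order all bursts by start time; count
  transitions where the next burst is on the same side; divide by the total
  number of bursts. Perfect alternation scores 0; all bursts on one side
  scores $(n-1)/n$, the maximum a transition count allows under the
  divide-by-total definition.
* **Simultaneous-burst penalty** — count bursts whose overlap with some
  contralateral burst exceeds 70% of the reference duration, divided by
  total bursts. The usual wording of this score leaves open 70% *of what*; the
  default takes each burst's own duration (each member of a coincident pair
  qualifies), with overlap-over-the-shorter-burst available as
  `overlap_denominator = "shorter"`. Zero-duration bursts qualify only when
  they fall strictly inside a contralateral burst.

Both scores are validated against brute-force enumerations over every
side-sequence of length ≤ 8, and are invariant to time shifts and to
swapping the channel labels.

## Activity traces, frequency, phase

Two per-channel activity traces are built per episode. The **envelope
trace** interpolates a cubic spline through the local maxima of the
rectified trace (a literal upper envelope; the analytic-signal magnitude is
the config alternative) and band-passes it to 10-40 Hz, zero-phase: apexes
align with bursts, troughs with inter-burst gaps — right for burst timing,
wrong for frequency analysis because the band cuts into the 20-60 Hz output
range. The **periodicity trace** rectifies and low-passes at 90 Hz
(zero-phase, order 4), then scales to roughly [0, 1]. The cutoff matters:
it leaves less than 10% amplitude distortion across the whole 10-60 Hz
tail-beat band while crushing the ~250 Hz within-burst spike structure.
Without that suppression the analytic phase is dominated by spike-scale
content and the left-right phase difference becomes meaningless.

Instantaneous tail-beat frequency is the ridge (per-time argmax of power)
of a Morlet CWT of the mean-removed periodicity trace over 10-60 Hz in
0.25 Hz steps, computed on an internally decimated ~1 kHz grid. Ridges are
extracted from a window padded by 0.15 s of surrounding quiescence and then
restricted to the episode: at 15 Hz the wavelet's cone of influence spans
roughly ±90 ms, and without the pad the edge ridge is dragged toward the
bout interior — the dominant error mode for short decelerating bouts.

The left-right **phase shift** is the circular mean of per-sample analytic
phase differences, and **coherence** is the mean resultant length (the
polar-plot radius), not spectral coherence. Instantaneous phase is only
well defined for narrow-band signals, so both traces are first confined to
0.6-1.6 times the left trace's spectral peak by a zero-phase filter; burst
trains are harmonic-rich, and skipping this step biases non-180° phase
shifts by several degrees. Identical traces bypass the filter and give 0°
at coherence exactly 1. On artefact-free synthetic data, injected phases of
90/135/180° are recovered within a few degrees at coherence above 0.9, and
injected constant frequencies of 15-45 Hz are recovered with mean absolute
error well under 1 Hz at noise 0.25 of spike amplitude.

## Bout classification

The ridge is lightly median-filtered (20 ms half-width, shrinking with bout
duration; the trend fit is already a power-weighted least squares, so heavy
smoothing only flattens short interior peaks) and the ends inside the cone
of influence are trimmed (75 ms, at most one eighth of the bout). The rules,
in order: `rise_fall` when the ridge maximum is interior (≥100 ms from both
edges) and both edge values sit ≥5 Hz below it; otherwise the sign of the
power-weighted slope, with $|slope| < 5$ Hz/s called `continuous`. A bout
whose left-right coherence falls below 0.3 is labelled `incoherent` — the
erratic/non-rhythmic class has no established quantitative criterion, so
this threshold is our documented rule. `crosses_30hz` is computed from the
smoothed ridge's extrema and is verified to be independent of the smoothing
width. On the generator's study conditions the four-class taxonomy is
recovered perfectly without noise and at ≥98% with noise.

The per-bout mean frequency is power-weighted by default (`"unweighted"`
available): the power weighting discounts ridge samples where the transform
has little energy, e.g. the first and last fractions of a cycle.

## Calcium alignment

`compute_dff()` uses a rolling 8th-percentile baseline over 10 s windows;
ΔF/F is then exactly invariant to multiplicative gain. `estimate_lag()`
cross-correlates the ROI-averaged ΔF/F with the bout indicator convolved
with a single-exponential calcium kernel (τ = 0.3 s by default — the
matched template). Correlating against the raw box indicator instead
displaces the peak by roughly the kernel centroid (~0.2 s at τ = 0.3 s);
the matched template removes that bias, and a parabolic refinement around
the correlation peak gives sub-frame resolution. Across frame rates of
30-100 Hz and lags of 0.1-0.5 s the estimator is accurate to well within
one frame period. An onset-difference estimator (`method = "onset_diff"`)
is provided because published lag values do not state which definition was
used; it reads systematically ~0.05-0.1 s longer, as expected for a
threshold-crossing definition on a finite-rise signal. Lag estimation
requires at least 3 bouts and searches [-0.5, 1.5] s.

## Numerical and degenerate-input policy

All times are seconds from recording start, frequencies Hz, phases degrees
in [0, 360). Non-finite samples, too-short windows, band edges at or above
Nyquist, non-positive ΔF/F baselines, empty frequency traces, and lag
estimation with fewer than 3 bouts raise errors naming the violated
constraint; empty detection results (silent traces) are valid and propagate
as empty tables. Zero-burst episodes make the penalties *undefined* (an
error), not zero. Every generated annotation is checked on construction:
spikes inside bursts, bursts inside bouts.

Reproducibility is exact: a `synth_config` seed fully determines the
recording bit-for-bit; `run_pipeline()` writes a manifest with a hash of
the scientific configuration (output paths excluded) and MD5s of every
output, and two runs with the same config and seed produce byte-identical
bundles.

## Problem sizes

The shipped analyses and tests run at deliberately modest scale: 10 kHz
synthetic sampling (the rate is a config field; real acquisitions at
50 kHz work unchanged), 3-6 s recordings for parameter-recovery suites,
60 s per preset for the workflow under `analysis/`, ~100 seeded recordings
for the boundary-exactness suite and ~200 bouts for the classification
suite. These sizes give stable statistics for every property tested while
keeping a full run of the test suite and analysis scripts comfortable on a
single CPU.

## Known limitations

* The CWT ridge is reliable only inside the 10-60 Hz analysis band;
  trajectories pinned at the band floor lose their lowest excursions.
* Episode extraction on recordings containing *no* activity can emit a few
  short spurious clusters (see above); they are flagged, not suppressed.
* The alternation penalty's transition count cannot reach 1 (maximum
  $(n-1)/n$); we keep the divide-by-total-bursts definition rather than
  renormalizing.
* Phase/coherence assume a common dominant rhythm; on `dual_frequency`
  artefact bouts the narrow-band filter follows the left channel, which is
  exactly what makes the left-right ridge discrepancy the better detector
  for that artefact.
* ROI segmentation of calcium movies is out of scope; the calcium module
  consumes already-extracted ROI traces.
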