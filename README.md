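# fictiveswim

Analysis of **fictive locomotion** in paralyzed zebrafish larvae recorded
with paired extracellular electrodes on contralateral hemi-segments of the
same body segment. A paralyzed larva's spinal network still produces swim
bouts: episodes of spike bursts that alternate between the left and right
side at tail-beat frequencies of 15–60 Hz, with the 30 Hz line separating
the slow and fast speed modules of the larval spinal cord. This package
turns the resulting two-channel voltage series into quantitative swim-bout
statistics, end to end:

* **Morlet-CWT wavelet denoising** of the raw traces (with the conventional
  100–1000 Hz zero-phase band-pass as a comparison baseline);
* **unbiased episode extraction** — peak detection on the denoised traces
  and single-linkage clustering of pooled spike times, with the single
  exclusion rule that episodes shorter than 100 ms are dropped;
* **burst segmentation** (8 ms gap rule) and two left–right coordination
  scores: the **alternation penalty** (same-side burst transitions over
  total bursts; 0 = perfect anti-phase alternation) and the
  **simultaneous-burst penalty** (bursts overlapping a contralateral burst
  by more than 70%, over total bursts);
* **activity traces** per episode: a 10–40 Hz band-passed upper envelope
  for burst timing, and an unfiltered "periodicity" trace that conserves
  frequency and phase information across the full 10–60 Hz output range;
* **instantaneous tail-beat frequency** as the ridge of a Morlet CWT of
  the periodicity trace; **phase shift and coherence** as the circular
  mean and mean resultant length of per-sample left–right analytic phase
  differences (the polar-plot statistics);
* **bout classification** into increasing / decreasing / continuous /
  rise-then-fall frequency trajectories (plus an incoherent flag), with
  exact 30 Hz-crossing bookkeeping;
* **calcium–electrophysiology alignment**: rolling-percentile ΔF/F,
  matched-template cross-correlation lag estimation, and per-ROI
  engagement scores.

Because raw recordings of this kind are generally not deposited, the
package includes a **seeded synthetic-recording generator** with complete
ground-truth annotation (bout windows, burst and spike times, injected
frequency trajectories, phase, calcium lag) emulating four stimulation
presets (spontaneous, NMDA, electrical, optomotor) and four artefact
classes (erratic bursting, dual-frequency output, incoherent activity,
stimulation artefacts). Every pipeline stage is validated against what the
generator injected; see `vignettes/fictive-swim-analysis.Rmd` for the
model, the design decisions and their rationale.

## Worked example

```r
library(fictiveswim)

# a 30 s optomotor-style recording with known ground truth
sim <- generate_recording(synth_config(duration_s = 30,
                                       preset = "optomotor", seed = 11))
den <- wavelet_denoise(sim$recording)
eps <- extract_episodes(den)
res <- run_pipeline(pipeline_config(out_dir = "out",
          synth = synth_config(duration_s = 30, preset = "optomotor",
                               seed = 11), seed = 11), quiet = TRUE)
res$bouts[, c("label", "crosses_30hz", "mean_freq_hz",
              "mean_phase_deg", "coherence", "alternation_penalty")]
#> # A tibble: 5 × 6
#>   label      crosses_30hz mean_freq_hz mean_phase_deg coherence alternation_penalty
#>   <chr>      <lgl>               <dbl>          <dbl>     <dbl>               <dbl>
#> 1 rise_fall  FALSE                34.7           182.     0.985              0
#> 2 rise_fall  FALSE                34.4           182.     0.990              0
#> 3 continuous FALSE                24.3           179.     0.883              0.0357
#> 4 increasing TRUE                 25.9           181.     0.917              0
#> 5 rise_fall  FALSE                35.9           181.     0.993              0
res$calcium$lag
#> <lag_estimate> 332 +- 0 ms (xcorr_peak)
```

Each row is one detected swim episode: its frequency-trajectory class,
whether its tail-beat frequency crossed the 30 Hz speed-module boundary,
its power-weighted mean frequency, the left–right phase shift (180° =
perfect anti-phase alternation) with its coherence, and the alternation
penalty (near 0 = clean alternation). The lag estimate recovers the 311 ms
calcium-onset delay injected into the simulated ROI traces to within the
30 Hz imaging frame period.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the package's built-in study
on synthetic data, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_recordings.R` | one 60 s recording per preset + per artefact class, with ground truth |
| `02_denoise_comparison.R`  | wavelet vs band-pass spike recovery at low SNR |
| `03_extract_episodes.R`    | episodes, bursts, penalty scores per preset |
| `04_rhythm_classification.R` | frequency, phase/coherence, bout classes, 30 Hz fractions |
| `05_calcium_alignment.R`   | ΔF/F, lag estimation and the lag-recovery grid |

Representative output (from `02` and `05`): at spike amplitudes of 2.5
noise SDs the identical peak detector recovers **34.3%** of ground-truth
spikes after wavelet denoising versus **19.3%** after conventional
band-pass filtering (at 4 noise SDs: 83.2% vs 67.2%), and the calcium lag
injected at 311 ms is estimated at **328 ms** by matched-template
cross-correlation, with worst-case error across the 30/60/100 Hz × 0.1/0.3/0.5 s
recovery grid of **0.55 frame periods**.

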