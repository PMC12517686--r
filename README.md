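# voltsync

Analysis of **synchronous ensembles of hippocampal CA1 pyramidal cells from
population voltage imaging**, recorded together with a contralateral LFP
channel and behavior tracking on a one-way track.

Population voltage imaging resolves both spikes and subthreshold membrane
voltage (subVm) from many neurons at once, at 2 kHz. During exploration of a
novel environment, CA1 pyramidal cells fire together in brief (~25 ms)
windows that recruit a large fraction (~40%) of the imaged population. These
synchronous ensembles are not ripple events — spiking is typically *silenced*
during contralateral ripples — but are phase-locked to theta oscillations,
ride on coherent intracellular theta, and preferentially link place cells
with *distinct* place fields. `voltsync` implements the full analysis chain
needed to establish those observations, plus a seeded synthetic-session
generator with a complete ground-truth ledger so that every detector can be
scored end to end.

## The core statistics

* **Spike detection from negative-going fluorescence.** Baseline
  `F0(t)` = mean of the raw trace within ±0.5 s; `dF/F = (F0 − F)/F0`; a
  5 ms running-median high-pass isolates transients; the detection threshold
  minimizes the estimated sum of type I and type II errors between the
  amplitude distributions of candidate transients and of local maxima of the
  *inverted* trace (the noise distribution); events below half the mean of
  the top-5% amplitudes are discarded. QC: SNR > 5, spike FWHM > 0.8 ms,
  rate > 0.1 Hz, soma distance ≥ 70 µm, ≥ 9 cells per session.
* **Population synchrony.** Total spike count in a sliding 25 ms window is
  compared with surrogates in which every spike is jittered within ±75 ms
  (500 iterations); events are maximal runs where the count exceeds the
  surrogate mean + 4 SD. Controls: burst-spike removal (ISI ≤ 10 ms) and a
  theta-cycle shuffle that permutes the cycle in which each spike occurred
  while preserving its theta phase.
* **Cross-correlograms.** Grand-average CCGs (1 ms bins, normalized by
  reference spikes × number of other cells) and pairwise CCGs with jitter
  significance; synchronization strength = observed peak (|lag| ≤ 30 ms) ÷
  mean jittered count in the same bin.
* **LFP oscillations.** Ripples: 120–240 Hz band-pass, Hilbert envelope
  low-passed at 20 Hz, events above mean + 3.5 SD containing a sample above
  mean + 7 SD and lasting ≥ 30 ms. Ripple-modulation index
  `(r_in − r_out)/(r_in + r_out)`. Theta phase-locking: amplitude-weighted
  resultant vector `V_k = A(t_k) e^{iφ(t_k)}` with strength `|ΣV|/Σ|V|`.
* **subVm dynamics.** Suprathreshold excursions of the slow trace are
  linearly interpolated away; synchrony- and spike-triggered subVm averages;
  pairwise cross-correlation and 4–12 Hz magnitude-squared coherence over
  1 s segments (50% overlap, 90% state rule), related to soma distance.
* **Spatial coding.** Occupancy-normalized tuning curves (36 bins on 90 cm,
  speed > 3 cm/s), spatial selectivity = 1 − circular variance, place cells
  at selectivity > 0.25 and peak > 1 Hz, and the Spearman association of
  pairwise synchronization strength with tuning-curve similarity.

## Worked example

```r
library(voltsync)

cfg     <- generator_config(seed = 42)      # 14 cells, 180 s, 2 kHz
session <- generate_session(cfg)            # bundle + ground-truth ledger

run <- run_pipeline(session$bundle, master_seed = 42,
                    n_jitters_sync = 500, n_jitters_ccg = 200,
                    n_shuffles = 500, max_pairs = 45)
str(run$summary)
```

```
List of 19
 $ n_cells_analyzable               : int 14
 $ median_rate_hz                   : num 3.81
 $ n_sync_events                    : int 222
 $ sync_rate_hz                     : num 1.23
 $ median_ensemble_size_pct         : num 50
 $ grand_ccg_fwhm_ms_mean           : num 28.5
 $ n_ripples                        : int 5
 $ sync_theta_strength              : num 0.84
 $ sync_theta_pref_deg              : num -46.7
 $ pct_sync_in_ripples              : num 0
 $ median_theta_coherence_immobility: num 0.584
 $ median_theta_coherence_locomotion: num 0.626
 $ pct_place_cells                  : num 42.9
 $ sync_vs_tuning_rho               : num -0.5
 ...
```

Reading this: all 14 cells pass QC at a median rate of 3.8 Hz; 222
synchronous events are detected (1.23 Hz) with a median ensemble of 50% of
cells; the session-average grand CCG is ~28 ms wide; none of the events
co-occur with the 5 detected ripples; events lock to theta (vector strength
0.84) near the late rising phase (−47°); subVm theta coherence is ~0.6; 43%
of cells qualify as place cells, and pairwise synchronization strength is
negatively associated with tuning similarity.

Because the session is synthetic, every detector can be scored against the
generator's ledger:

```r
compare_to_truth(run, session$truth)
#> spike_sensitivity 0.996, spike_precision 0.968, ripple_recall 1,
#> ripple_precision 1, field_center_mae_cm 2.5, ...
```

Result objects are tidyverse-friendly: `tidy()`/`glance()` return tibbles
and `autoplot()` draws the standard figures (correlograms, event rasters,
tuning curves).

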