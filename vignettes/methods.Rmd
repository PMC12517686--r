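---
title: "Methods: detecting synchronous CA1 ensembles in population voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting synchronous CA1 ensembles in population voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures behind `voltsync`, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-session generator does and does not emulate, and the numerical
choices taken where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. Data model

A session couples three simultaneously recorded streams on two timebases:
per-cell fluorescence at the imaging rate (2 kHz), one LFP channel at an
integer multiple of it (8 kHz), and behavior (linearized position in cm and
speed in cm/s) stored at the imaging rate. Imaging frame 0 defines `t = 0`,
and sample `i` covers the half-open interval `[i/fs, (i+1)/fs)`; event times
map to sample indices by nearest-sample rounding with a half-up tie-break.
Units are seconds, cm, Hz, micrometers and radians throughout; degrees
appear only in reports. The on-disk bundle is a directory of plain-text
files (`session.json` plus CSV payloads written at `%.17g`), which makes
save/load round trips bit-identical and repeated saves byte-identical.

## 2. From fluorescence to spikes and subVm

The sensor is negative-going: depolarization darkens the cell. The baseline
`F0(t)` is the moving average of the raw trace over ±0.5 s (edge windows
shrink; no synthetic padding anywhere in the package), and
`dF/F = (F0 − F)/F0`, so spikes become positive transients while bleaching
on timescales much slower than 1 s cancels. A 5 ms running-median high-pass
(`runmed`, shrunken end windows) isolates the fast transients.

**Detection threshold.** Candidate transients are strict local maxima of the
residual; the noise amplitude distribution is formed from local maxima of
the inverted residual. The threshold minimizes
`(fraction of noise maxima ≥ θ) + (fraction of candidates < θ)` over the
pooled amplitude grid, taking the smallest θ on ties. Two properties matter
in practice. First, with genuine spikes present the minimum sits just above
the noise support, because only there does the candidate CDF exceed the
noise CDF by the spike mass. Second, on a spikeless trace the two empirical
CDFs coincide up to sampling noise, the objective is flat near 1, and the
minimizer is essentially arbitrary — the estimator is not designed to
control the false-positive rate in the no-signal regime, and the test suite
asserts only that the threshold suppresses the majority of noise maxima
there. After thresholding, events with amplitude below half the **mean of
the top 5%** of kept amplitudes are discarded (mean rather than the 95th
percentile, for robustness at small counts); spike times are refined to
sub-sample precision by three-point parabolic interpolation.

**SNR and QC.** SNR is the mean spike amplitude over the SD of the residual
with `[t − 2 ms, t + 4 ms]` around every spike deleted. Cells pass QC with
SNR > 5, spike-waveform FWHM > 0.8 ms (measured on the spike-triggered mean
residual in ±5 ms, with linear interpolation at the half-max crossings), and
mean rate > 0.1 Hz; of any centroid pair closer than 70 µm the lower-SNR
member is dropped greedily; a session is analyzable with ≥ 9 surviving
cells.

**subVm.** The slow trace is `dF/F − residual`. The spike threshold voltage
is the value of the spike-triggered mean dF/F waveform at the sample
preceding the largest step of its first derivative; all slow-trace samples
above it are replaced by linear interpolation between the nearest flanking
subthreshold samples (nearest-value extension at the trace boundary). The
extracted subVm therefore never exceeds the spike threshold.

## 3. Behavior

Locomotion is speed > 3 cm/s, immobility < 1 cm/s, the band between is
unclassified; labels are pure per-sample thresholds merged into maximal
half-open intervals, with no hysteresis or minimum duration. Rate–speed
correlations convolve the spike train with a unit-area Gaussian whose
**FWHM** is 250 ms (σ ≈ 106 ms) — the FWHM reading was chosen over σ since
the kernel is quoted as a "window", and windows are conventionally quoted by
width.

## 4. Population synchrony

The population count is the total number of spikes across analyzable cells
in a sliding 25 ms window evaluated at every imaging sample (step = 1
sample, i.e. 0.5 ms). Surrogates displace every spike independently by a
continuous uniform offset on ±75 ms, clipped to the session, 500 times;
events are maximal runs where the observed count exceeds the per-sample
surrogate mean + 4 SD, timestamped at the run midpoint. Participants are
cells with at least one spike within ±12.5 ms of the event time, and the
ensemble size is the participant percentage of analyzable cells. Because
any cell whose background spike happens to fall in that window counts as a
participant, measured ensemble sizes run roughly one cell above the
configured participation at ordinary CA1 rates.

Two controls mirror the analysis: burst-follower removal (a spike is a
burst follower if its preceding ISI ≤ 10 ms; the initiating spike is kept),
and the theta-cycle shuffle, which redraws each spike's theta cycle
uniformly (with replacement) among the session's cycles while preserving
its phase, inverting phase to time by linear interpolation of the unwrapped
phase within the target cycle. Cycles are delimited by ascending
zero-phase crossings; non-monotone cycles are excluded from the draw.

A detectability note: with 14 cells, 40% participation and ~3 Hz background
rates, the median ensemble count sits almost exactly at the mean + 4 SD
surrogate threshold, so the binomial lower tail of true ensembles is
undetectable by construction; detected-event statistics (for example the
median ensemble size) are therefore conditioned on detection. The recovery
tests quantify hit rate in the ensemble-rich regime (~1 Hz of events,
fixed 60% participation), where the threshold is cleared with margin.

## 5. Correlograms

Grand-average CCGs histogram `t_other − t_ref` over ±500 ms in 1 ms bins and
divide by (reference spikes × number of other cells); pairwise CCGs use raw
counts and require more than 100 counts in the window. The pairwise peak is
the maximum within |lag| ≤ 30 ms (ties: smaller |lag|, then negative first);
significance jitters the target train within ±75 ms (default 1000
iterations) with the add-one estimator `p = (1 + #{jittered peaks ≥
observed}) / (1 + n)`; synchronization strength divides the observed peak by
the mean jittered count in the same bin. Under independence the *peak* is a
maximum over 61 bins, so the null strength exceeds 1 by the max-of-bins
bias at low counts — null calibration in the tests is therefore done
against strengths produced by the identical procedure on pre-jittered
targets, not against the constant 1.

**FWHM.** The baseline is the mean of bins with |lag| > 400 ms and the width
is read at half of (peak − baseline) with linear interpolation at the
crossings. The crossing search runs on the 5-point-smoothed correlogram: at
realistic counts (3 Hz cells, 180 s) single-bin noise is about a quarter of
the half-height contrast, and raw-bin crossings would land next to the peak
bin, measuring noise rather than width. This smoothing adds ~2 ms² to the
squared width of a Gaussian peak — negligible for the 15–40 ms peaks of
interest. Session-level width is measured on the bin-wise average of the
per-cell grand CCGs (`average_ccgs()`).

## 6. LFP oscillations

Filters are zero-phase (forward–backward) Butterworth: order 4 for the
ripple (120–240 Hz) and theta (4–12 Hz) bands, order 2 for the 20 Hz
envelope low-pass. Narrow low bands far below the Nyquist rate (theta at
8 kHz has normalized cutoffs ~10⁻³) are numerically unstable in polynomial
form, so such signals are decimated after an anti-alias low-pass, filtered
at the reduced rate, and interpolated back — exact for the band-limited
result. The analytic signal is the standard FFT construction; phase 0 is
the oscillation peak and ±π the trough, and ripple events are maximal runs
of the smoothed envelope above mean + 3.5 SD containing a sample above
mean + 7 SD and lasting ≥ 30 ms. Envelope statistics use the whole trace;
at the ripple densities considered here (≲ 0.15 Hz of immobility) the
inflation from in-event samples is immaterial. Runs touching the first or
last 100 ms are discarded as filter transients.

Phase-locking of point events uses the amplitude-weighted resultant
`V_k = A(t_k) e^{iφ(t_k)}`: strength `|ΣV|/Σ|V|` ∈ [0, 1], preferred phase
`arg ΣV`, with significance from uniform redraws of the event times (1000
by default, optionally restricted to given state intervals). The
ripple-modulation index `(r_in − r_out)/(r_in + r_out)` takes its null from
circular time-shifts of the whole train, which preserve ISI structure.

## 7. subVm dynamics

Synchrony-triggered subVm averages use ±300 ms windows and discard any
window in which the cell fired (so spike waveforms cannot masquerade as
depolarization); spike-triggered averages require at least 5 triggers per
category. Pairwise analyses divide the session into 1 s segments with 50%
overlap, labeled immobility/locomotion when speed is on the right side of
the threshold for more than 90% of the segment; segments align across cells
by construction (simultaneous recording). Cross-correlation z-scores each
segment and normalizes by (n − 1) so the autocorrelation peaks at exactly 1;
positive lag means the second cell lags the first. Coherence within a 1 s
segment is estimated by Welch's method with 0.5 s Hann windows at 50%
overlap (3 windows; a single-window estimate is identically 1), averaged
over 4–12 Hz and then over same-state segments. With 3 windows the
independent-signal bias floor is ≈ 1/3; tests calibrate against that floor
rather than against zero.

## 8. Spatial coding

Tuning curves divide the 90 cm track into 36 half-open 2.5 cm bins and
divide speed-filtered (> 3 cm/s) spike counts by speed-filtered dwell time;
zero-occupancy bins are masked, never zero-filled. Selectivity maps bin
centers to angles `θ_b = 2π(b + 0.5)/36` (the one-way loop is treated as a
circle — the only reading under which circular variance is well defined) and
takes the rate-weighted mean resultant length. Place cells require
selectivity > 0.25 (strict) and peak rate > 1 Hz (strict). Tuning
similarity is Spearman over jointly defined bins; the synchrony–tuning
association is Spearman between state-restricted pairwise synchronization
strengths and similarities, with a permutation p-value.

## 9. The synthetic-session generator

The generator produces, from one mandatory seed, a full session bundle plus
a ledger (true spikes, sync events with participants, place-field centers,
theta phase, ripple intervals, state schedule, true subVm) sufficient to
score every detector. Its defaults encode the study conditions: 14 cells,
180 s at 2 kHz (LFP 8 kHz), 90 cm track; locomotion bouts (exponential,
mean 8 s) alternating with immobility (mean 5.5 s) through 1 s speed ramps,
targeting ≈ 55/35/10% of time with locomotion speed ~N(8.3, 2²) cm/s;
theta at 8 Hz (locomotion) / 7 Hz (immobility) with smooth transitions over
pink noise; ripples (150–200 Hz, 60–110 ms Hann bursts — typical CA1
episode lengths, so the 30 ms duration rule is not the binding constraint
at threshold amplitudes) only in immobility at 0.04 Hz, at 8× the
background ripple-band SD; lognormal baseline rates (median 3 Hz) raised
1.5× in immobility; synchronous ensembles as a 1 Hz Poisson process placed
at von Mises (κ = 4) theta phases around the late rising phase (−45°), each
recruiting cells with probability 0.4 for one spike within ±12.5 ms;
background spikes von Mises-locked to theta at κ = 0.5 — deliberately weaker
than the ensembles, matching the observation that spikes outside
synchronous events are less theta-modulated, and necessary for the
theta-cycle-shuffle control to bite (with equally strong background locking,
cycle-homogeneous coincidences dominate and shuffling cannot reduce the
event rate); 40% of cells get Gaussian place fields (σ = 5 cm) modulating
locomotion intensity; all spiking silenced inside ripples; a 2 ms refractory
period in which ensemble spikes win conflicts.

Rendering: true subVm mixes three spatially smooth theta sources (Gaussian
weight fields, 400 µm length scale, independent ~2 Hz amplitude envelopes
and small fixed phase offsets) — nearby cells receive nearly identical
mixtures, so theta coherence falls with centroid distance — plus
independent slow noise and a 10 ms-σ depolarizing bump at each ensemble
time. Spikes add a biexponential transient (FWHM ≈ 1 ms) whose sampled peak
is aligned to the spike time. The sensor model is
`raw = F_base · e^{−t/τ_bleach} (1 − dFF_true) + white noise`; the default
transient amplitude (6% dF/F) over noise (0.4% of baseline) puts cells in
the SNR ≈ 8–10 regime the QC thresholds presuppose — the 5 ms median
high-pass unavoidably absorbs ~20% of a 1 ms transient, which the amplitude
choice accounts for. An optional mode for tuning-versus-synchrony tests
assigns cells to two alternating assemblies and gives same-assembly cells
maximally spaced fields while opposite-assembly cells get nearly
overlapping fields (offset 0.8 σ), making field overlap anti-correlate with
shared participation.

What the generator does **not** emulate: sensor nonlinearity and
photobleaching-dependent noise, movement artifacts and ROI crosstalk, spike
waveform diversity (bursts carry no amplitude attenuation), theta phase
precession, lap-to-lap field dynamics, and ripple-locked replay content.
Passing tests therefore certify the analysis chain against the statistical
structure the methods assume, not against every property of real
recordings.

## 10. Problem sizes, seeds, reproducibility

Every stochastic operation takes an explicit seed, restores the caller's
RNG state, and the pipeline derives per-stage seeds from one master seed by
fixed offsets, making summary JSON byte-identical across reruns. The test
suite works on one cached default session (seed 7) plus smaller purpose-
built sessions (60 s) and desk-scale constructions; the null-calibration
check uses 200 Poisson pairs at 5 Hz with 200 jitter iterations per pair;
the ripple-recovery check pools two sessions at 0.15 Hz immobility ripple
rate (the default 0.04 Hz yields only a couple of events per session, too
few to estimate recall). These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs in a few minutes.

## 11. Known limitations

* The type I + II threshold estimator has no false-positive guarantee on
  spikeless traces (§2); real use assumes cells fire.
* Sliding-window synchrony near the detection threshold conditions detected
  ensembles on size (§4); comparisons of ensemble-size distributions across
  conditions inherit that bias exactly as the original procedure does.
* Pairwise synchronization strength is peak-based and therefore biased
  above 1 under independence at low counts; compare it against the jitter
  null, not against 1.
* The coherence estimator's bias floor (≈ 1/3 with 3 Welch windows) is a
  property of the segment length the procedure fixes at 1 s; absolute
  coherence values should be read relative to that floor.
* State classification has no hysteresis, so brief threshold crossings
  fragment intervals; downstream statistics treat those fragments as
  legitimate single-sample states.
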