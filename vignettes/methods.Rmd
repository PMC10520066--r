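---
title: "Methods: sleep staging and spectral HRV in somnark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging and spectral HRV in somnark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnark)
```

somnark implements a complete analysis chain for rodent polysomnography:
EEG and EMG are reduced to per-epoch spectral features, thresholded into
active waking (AW), quiet sleep (QS) and paradoxical sleep (PS), and
summarized as sleep-architecture metrics; the ECG is reduced to an RR
tachogram whose low-frequency (LF) and high-frequency (HF) spectral powers
index sympathetic and vagal cardiac modulation, conditioned on sleep stage.
A seeded synthetic-signal generator provides ground-truth recordings so the
whole chain is testable without animal data. This vignette explains the
models, the defaults, and the choices made where the design was genuinely
open.

## Signal model and acquisition constants

The package models a three-channel wireless acquisition setup: EEG sampled
at 125 Hz (0.16–48 Hz passband), EMG at 250 Hz (34–103 Hz), ECG at 500 Hz
(0.72–103 Hz), synchronously digitized. These rates are fixed constants of
the data model; `read_recording()` validates them when mapping EDF channels
to roles.

## Spectral features

`sliding_spectrum()` cuts a trace into 16 s windows with 50% overlap (8 s
hop, matching the 8 s epoch), removes each window's mean, applies a Hamming
taper and computes a one-sided FFT periodogram at 1/16 Hz resolution. Bin
powers are normalized so their sum equals the taper-corrected window
variance (Parseval); the tests assert this identity to 1e-6.

Each 8 s epoch receives the features of the 16 s window *starting* at the
epoch's start, so a window covers its epoch and the next; the trailing
epoch without a full window is dropped. This forward alignment is the
simplest mapping consistent with 16 s windows at 50% overlap scoring 8 s
epochs. Its one visible consequence is discussed under *Known limitations*.

Features per epoch:

* **MPF** — power-weighted mean frequency over 1–32 Hz. The integration
  band is the union of the four named EEG bands (delta 1–4, theta 4–8,
  alpha 8–13, beta 13–32 Hz), inside the EEG passband. Band edges are
  half-open `[lo, hi)` — a bin at exactly 4 Hz is theta — with the top
  beta edge closed so the four bands partition 1–32 Hz exactly and the
  fractions sum to 1.
* **EMG power** — summed spectral power over the 34–103 Hz passband.
* **Band fractions** — delta/theta/alpha/beta shares of total 1–32 Hz
  power (normalized units).

Per-window periodograms are used rather than Welch averaging because the
features are needed per epoch, not globally.

## Sleep staging

Staging uses two data-driven thresholds per 5 h segment (a final partial
segment of at least 30 minutes gets its own thresholds; a shorter one
reuses the previous segment's). The MPF histogram separates QS (low MPF)
from the AW/PS complex; the log-EMG-power histogram separates AW (high
EMG) from the QS/PS complex. Each threshold is the one-dimensional
between-class-variance-maximizing split (`otsu_split()`), the automatic
analogue of a rater's placement between the two histogram modes. Manual
overrides are accepted and recorded in the provenance (`source` column).

Two guards replace the judgment of an experienced rater when a histogram
is effectively unimodal:

* Sarle's bimodality coefficient below 5/9 raises a warning.
* If the two classes produced by the split sit closer than the physiologic
  contrast (1.5 Hz for MPF; a factor `exp(1.5)` ≈ 4.5 for EMG power), the
  split is within a single population. The threshold is then placed
  outside the histogram: for EMG all epochs are treated as sleep-level
  (absence of a high-EMG waking population is the typical cause, e.g. a
  segment with no waking); for MPF the side is chosen by delta-dominance
  (mean delta fraction above 0.5 means the single population is QS).

Classification is the exhaustive four-way rule: MPF above threshold and
EMG above is AW; both below (non-strict) is QS; MPF above with EMG below
is PS; MPF below with EMG above is physiologically implausible and marked
ERR, excluded from all downstream rates. "Above" is strict; ties on
continuous features are measure-zero so the convention is immaterial.

A stage (bout) is a maximal run of at least 6 identical consecutive non-ERR
epochs; any shorter run is one interruption event. ERR epochs split runs
and belong to neither. Architecture metrics:

* per-stage time as % of valid (non-ERR) epochs and mean bout duration;
* **interruption rate** — interruption events per valid minute. This is
  the default fragmentation metric and the one reported in the package's
  sleep-structure table;
* **QS interruption rate** — a stricter variant counting brief awakenings
  only: short AW runs whose nearest non-ERR neighbour on each side is QS,
  per QS minute. Short PS runs inside QS are ordinary QS–PS transition
  attempts, not arousals, and are excluded;
* the six ordered stage-transition counts between consecutive bouts
  (interruption runs are skipped, since transitions are defined between
  formed stages);
* mean QS band fractions in percent (normalized units).

## HRV chain

`detect_r_peaks()` is a Pan–Tompkins-style detector: 5–40 Hz zero-phase
band-pass, squaring, 150 ms moving-window integration, adaptive threshold
with a 60 ms refractory period, one detection per contiguous
above-threshold region (a single QRS's integration plateau can hold
several local maxima, so per-maximum acceptance would double-fire at rat
RR of ~200 ms), and refinement to the lightly smoothed raw-trace maximum
within ±40 ms.

RR intervals outside 100–350 ms (physiologic bounds for rat), or deviating
more than 30% from the running median of the surrounding nine intervals,
are masked as artifacts. The unmasked tachogram (each RR anchored at the
beat closing it) is cubic-spline interpolated onto a uniform 64 Hz grid —
cubic rather than linear for smoother spectra — and cut into 1024-point
(16 s) segments with 50% overlap. Each segment is mean-removed, Hamming
tapered and Fourier transformed; LF is the summed power over
[0.06, 0.6) Hz and HF over [0.6, 2.4] Hz (rat-specific bands; the shared
0.6 Hz edge belongs to HF, and at 1/16 Hz resolution no bin falls at
0.06 Hz).

A segment is assigned a sleep stage only when every epoch it overlaps
carries the same non-ERR label (a majority-vote option exists). Per stage
and overall, the summary reports mean RR, `log_lf`, `log_hf` (natural
logs) and `log_lfhf = log_lf − log_hf`. The natural log is used because
the published log-scale LF/HF values equal the difference of the published
log LF and log HF, and e-scaled powers are physiologic for rat. The log is
applied to the per-stratum *mean* band power by default
(`log_order = "log_of_mean"`); averaging per-segment logs is available.
Stages with no assigned segments are reported absent, not zero.

## Two-group statistics

`compare_groups()` implements the normality-gated policy: Shapiro–Wilk per
group at α = 0.05 (the gate level is a package choice; only the gate
itself is prescribed), pooled (equal-variance) Student's t if both groups
pass, otherwise the Mann–Whitney U test — exact for groups of up to eight
without ties, normal approximation with tie and continuity correction
above. The equal-variance form is used because it reproduces published
p-values recomputed from printed mean ± SD summaries
(`pooled_t_from_summary()`). `build_report()` assembles mean ± SD per
group with p to three decimals, one row per metric; rows carry the
configuration hash and tables from different hashes refuse to pool.

No multiple-testing correction is applied, deliberately; the reports are
descriptive reproductions of per-row tests.

## The synthetic generator

`generate_recording()` draws, from one seed expanded into fixed
per-channel child streams:

* **Hypnogram** — a semi-Markov chain over AW/QS/PS with geometric bout
  lengths at the configured per-stage means (memoryless, the simplest
  model satisfying the ≥6-epoch bout statistics). Stage entries follow a
  reversible zero-diagonal transition matrix whose stationary visit
  distribution is proportional to `stage_mix / stage_mean_bouts`, so
  realized time fractions track the configured mix (a naive "next stage
  proportional to weight" rule skews them). Brief awakenings are then
  injected *inside* QS bouts as a Poisson process (`qs_interruption_rate`
  per QS minute), each 1–5 epochs, leaving at least one QS epoch on each side; the pre-injection QS share is inflated to offset the QS→AW
  conversion. When the configured mix, bout lengths and interruption rate
  are jointly infeasible (very high interruption rates with a small AW
  share), the generator prioritizes interruption realism and clips the
  natural AW share at zero, so realized mixes can deviate from extreme
  targets; the control-like defaults are comfortably feasible.
* **EEG** — per band (delta/theta/alpha/beta), Gaussian noise shaped by a
  steep zero-phase Butterworth band-pass applied exactly in the frequency
  domain (the |H|² magnitude response on the FFT grid — identical to
  forward–backward filtering without edge transients, and O(n log n)).
  An 8th-order band-pass is used because gentler skirts leak a visible
  share of delta power into the theta band. Per-stage weights set each
  band's power share; gains cross-fade over ≤0.5 s at stage changes so
  there are no clicks at epoch joins.
* **EMG** — 34–103 Hz noise with per-stage RMS gain (AW 10, QS 1,
  PS 0.8). PS is set close to QS deliberately: the EMG histogram of the
  modelled data has *two* populations (AW versus the QS/PS complex), and
  a strongly atonic PS would create a third mode that no two-population
  threshold can respect.
* **ECG** — integral pulse frequency modulation: beats fire when the
  integral of the instantaneous rate `1000/RR(t)` crosses an integer,
  with `RR(t) = mean_rr + lf_amp[stage]·sin(2π·0.3t) +
  hf_amp[stage]·sin(2π·1.2t) + noise` (ms). A 40 ms raised-cosine spike
  of unit amplitude marks each beat — sufficient for R-peak detection; no
  P/T waves.

Default conditions mimic a control rat: mix 11/48/41% AW/QS/PS, mean
bouts 12/20/12 epochs, 0.35 interruptions per QS minute, delta-dominant
QS EEG (88/7/2.5/2.5%), mean RR 198 ms, and LF/HF modulation amplitudes
chosen so the log band powers land in the published physiologic range
(e.g. QS LF amplitude 4.1 ms ≈ e^2.13/2 ms² of LF power). The
exposure-like preset (`sim_config_pm25()`) raises the QS interruption
rate to 0.52 per QS minute and the QS LF amplitude to 5.3 ms (a +0.5
shift in QS log LF/HF), with a slightly less delta-dominant QS EEG —
mimicking the reported phenotype of acute fine-particulate exposure at
the signal-statistics level only. No toxicology, inflammation or protein
biology is modelled.

What the generator does *not* emulate: real EEG 1/f background and
artifacts, ECG morphology beyond the R spike, electrode noise,
within-animal day-to-day structure (it produces single continuous
sessions; multi-day stitching is left to the caller), and between-animal
variability beyond seed-to-seed randomness. Tests passing on synthetic
recordings therefore validate the chain's correctness and calibration,
not its robustness to real-world artifacts.

## Numerical choices and degenerate inputs

* Periodogram normalization: `sum(P) = sum((x−mean)·w)² / sum(w²)`; exact
  by Parseval, so band powers are in squared signal units (ms² for RR).
* The IPFM integral is accumulated on the 500 Hz grid and beat times are
  found by linear interpolation of the cumulative rate — exact for
  constant RR.
* Beat-interval sampling low-passes RR modulation (interval averaging):
  at 1.2 Hz with 200 ms beats the recovered HF power is attenuated by
  ≈ sinc²(π·f·RR) ≈ 0.82. Spectral recovery is therefore asserted on the
  uniform series (within 15% of A²/2), while the full chain is checked by
  the quadratic power-law in amplitude, which the attenuation preserves.
* Zero in-band power raises an error in `mean_power_frequency()` and
  `band_power_fractions()`; all-masked tachograms and all-ERR label
  series degrade with warnings or absent strata rather than silent zeros.
* `pooled_t_from_summary()` returns p = 1 for identical degenerate
  summaries (both SDs zero, equal means) by convention.

## Scale of the validation experiments

The test-suite replicate studies run at desk scale, chosen as the package's
own operating points: staging recovery on one 30-minute recording
(accuracy ≥ 0.90 against ground truth); null calibration of the QS LF/HF
comparison on twenty 6-vs-6 replicates of 10-minute recordings through the
ECG chain; and the two-preset directional study on twenty 6-vs-6 cohorts
of 50-minute recordings through the full pipeline. Fifty-minute cohorts
put roughly 130 QS minutes per arm in each replicate, enough for the
interruption-rate contrast (a count statistic whose dispersion is set by
the geometric bout model as much as by Poisson noise) to resolve its
direction reliably; the LF/HF contrast is far better resolved and does
not constrain the scale.

## Known limitations

* The forward window→epoch alignment smears a state change into the
  preceding epoch's features: a 1–5-epoch awakening is typically detected
  one epoch longer than injected, so a 5-epoch intrusion can reach the
  6-epoch bout rule and stop counting as an interruption. Measured
  interruption rates are therefore calibrated slightly below configured
  ones; group contrasts are preserved.
* Otsu thresholds assume two populations per histogram. The guards above
  catch unimodal segments, but a genuinely trimodal histogram (e.g. an
  intermediate-EMG artifact class) would still be split two ways.
* Exact Mann–Whitney p-values are only available without ties; tied data
  fall back to the corrected normal approximation regardless of group
  size.
* EDF export quantizes to 16 bits over the per-channel range; the
  internal serialized container is provided for lossless round trips.
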