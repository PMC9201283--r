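---
title: "Methods: murine cardiovascular autonomic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: murine cardiovascular autonomic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murinecv)
```

## Scope and data model

`murinecv` quantifies cardiovascular autonomic function in mice from
two-channel recordings: an ECG (mV) and, optionally, arterial blood
pressure (mmHg), sampled on a common clock (the laboratory convention is
4 kHz for 15-minute sessions under light anaesthesia). All stages operate
on a single currency, the *beat series*: strictly increasing R-peak times
`t` (s), the R-R tachogram `rr[i] = 1000 * (t[i+1] - t[i])` (ms), optional
beat-wise systolic pressure (mmHg), and per-beat validity flags. Times are
always seconds, intervals milliseconds, pressures mmHg, frequencies Hz and
spectral powers ms²; unit conversion happens only at the I/O boundary.

The native file format is delimited text with a one-line JSON header
(sampling rate, units, channels, subject metadata); a text variant of
waveform-database-style paired header/sample files is read-only. Beat
tables are plain TSV. Proprietary acquisition formats are out of scope.

## Beat detection and artifact screening

R peaks are found Pan-Tompkins style: zero-phase Butterworth band-pass
(10 Hz to min(150, 0.45·fs) Hz), squaring, a ~10 ms moving-average energy
envelope, and an adaptive threshold set to a fraction of the median of
per-second envelope maxima — the median makes the threshold robust to an
isolated artifact dominating the amplitude scale. Candidates are refined
to the local raw-ECG maximum within ±10 ms and subjected to a refractory
period (default 40 ms, well below the murine R-R range of 80–150 ms).

The study this pipeline operationalises selected "stable, artifact-free"
sections manually; we automate that with explicit, logged rules:

* an interval outside the physiological range (default 50–250 ms) flags
  both beats bounding it;
* a relative beat-to-beat change above the ectopy threshold (default 30%)
  flags the beat shared by the two intervals;
* screening only ever adds flags, so it is idempotent.

Analysis segments (default 180 s for HRV/ECG, 300 s for baroreflex) are
chosen by sliding a window one beat at a time and minimising the flagged
fraction, ties broken by the earliest start; the best window must reject
at most 5% of beats. The positioning of sections inside the recording is
therefore deterministic and auditable, which a manual operator choice is
not; the log records every selection and exclusion.

## Heart rate variability

*Time domain.* SDNN is the sample (n−1) standard deviation of valid
intervals; RMSSD the root mean square of successive differences, with
differences that span an artifact gap excluded.

*Non-linear domain.* The Poincaré descriptors SD1/SD2 are included as the
standard minimal non-linear pair. SD1 is defined through the second
moment of successive differences, `SD1 = sqrt(mean(d²)/2)`, so the
algebraic identity `SD1 = RMSSD/sqrt(2)` holds to machine precision; SD2
uses the population variance, `SD2 = sqrt(2·varp(rr) − mean(d²)/2)`,
floored at zero (the floor only binds for strictly alternating series).
Reported SDNN keeps the n−1 convention; both conventions are tested.

*Frequency domain.* The tachogram is unevenly sampled by nature, so
spectra use the classical Lomb-Scargle periodogram (tau-shifted form) on
the mean-subtracted tachogram — no resampling, no interpolation, and
invalid beats are simply omitted. Each raw ordinate equals half the
sum-of-squares reduction of a least-squares sine-plus-cosine fit at that
frequency, which the test suite pins to an explicit regression oracle at
1e-8 relative. Ordinates are scaled by `2·T/n` (T = observation span) to
a one-sided density in ms²/Hz, chosen so that the trapezoidal band
integral returns the variance a band contributes: a sinusoid of amplitude
*A* integrates to *A²/2*. The default grid is 0.02–5 Hz with an
oversampling factor of 4 relative to 1/T. Murine bands are LF
0.10–1.00 Hz and HF 1.00–5.00 Hz; LF/HF is their ratio.

Interval values are attached to the time of the beat that ends the
interval; for band power this choice only shifts phase, not amplitude.

## Baroreflex sensitivity (sequence method)

A baroreflex sequence is a maximal run of at least 3 consecutive beats in
which systolic pressure and the R-R interval change concordantly beat
over beat (both rising: *up*; both falling: *down*). Following the
source convention — and unlike many sequence-method defaults — **no**
thresholds are applied to the SBP change, the R-R change or the
correlation coefficient; this choice is pinned by tests. A zero change in
either signal breaks a run; opposite-direction runs may share a pivot
beat. Each sequence contributes the ordinary least-squares slope of RR on
SBP (ms/mmHg); the reported gain is the unweighted mean over all
sequences, pooled across directions, with per-direction means alongside.
The SBP–RR lag is configurable 0–2 beats, default 0 (each systolic value
pairs with the interval that starts at the same beat). Aggregation by
unweighted pooled mean is our choice where the source is silent;
length- or r-weighted variants were rejected to keep the estimator free
of the thresholds the source explicitly renounces.

Beat-wise systolic pressure is assigned as the maximum of the pressure
waveform over the half-open cycle `[t[i], t[i+1])` anchored at the R
peak — an unambiguous convention for pairing pressures with intervals.

## QT and Mitchell's correction

QT is measured on an ensemble-averaged beat (pointwise mean of R-aligned
windows, default −30 to +80 ms, at least 30 usable beats; beats whose
window overlaps an invalid beat are excluded). The isoelectric baseline
is the median of the −30 to −20 ms pre-R window (murine PR segment).
Q onset is found scanning backwards from R for the first sample where the
derivative re-enters a ±2%-of-max-QRS-slope band around the baseline
slope, sustained ≥ 0.5 ms — the sustain requirement prevents the
momentary zero slope at the Q nadir from masquerading as onset. T end is
the first sample after the T apex within 5% of the T amplitude of
baseline for ≥ 2 ms; a T deflection below 3× the baseline noise is an
explicit "unmeasurable" error rather than a silent zero. Both rules are
invariant to DC offset and global gain. The murine rate correction is
Mitchell's formula `QTc = QT/sqrt(RR/100)` (all in ms), the identity at
RR = 100 ms, with the mean valid R-R of the same section.

## Group statistics

The design is fully crossed 2×2×2: genotype (WT/TG) × sex (M/F) × age
(6/12 months). The model is a fixed-effects linear model with all
interactions, sum-to-zero coding, and type-III (marginal) sums of
squares — appropriate because realistic cohorts are unbalanced (the
default simulated cell sizes, 8–23, mirror that). "Three-way measures"
is interpreted as between-subjects: no factor is repeated within animal.
Post-hoc comparisons are restricted to the 12 cell pairs differing in
exactly one factor (each of 8 cells has 3 one-factor neighbours;
8·3/2 = 12), tested on cell means against the pooled residual mean
square with its N−8 degrees of freedom, and Sidak-adjusted with family
size m = 12: `p_adj = 1 − (1 − p)^m`. The family size is configurable in
principle by adjusting the contrast table; 12 matches the stated
restriction. Type-I calibration is verified empirically: over 1000 null
simulations each effect rejects at 5% ± 2%.

## Synthetic ground truth

The generators emulate exactly the statistical structure the analysis
assumes, so every stage is testable without animal data:

* `sim_rr_series()` builds beat times iteratively
  (`t[k+1] = t[k] + rr(t[k])/1000`, an integral-pulse-style construction)
  with `rr(t)` the sum of a mean (120 ms), LF (0.4 Hz) and HF (2.5 Hz)
  sinusoids and Gaussian noise; the truth record carries the analytic
  band powers `amp²/2`. Building times from intervals, rather than
  resampling a tachogram, exercises the uneven-sampling path natively.
* `sim_coupled_sbp()` drives SBP along programmed ramps (default 6-beat
  ramps of 2 mmHg/beat separated by 3-beat plateaus) and rewrites RR as
  the linear reflex `rr = gain·sbp + intercept + noise`; annotations
  record each induced concordant run, which coincides with
  `find_sequences()` output at zero noise.
* `sim_ecg()` renders Gaussian-kernel PQRST complexes (R = 1 mV) with the
  Q onset fixed 8 ms before R and the T kernel placed so the 5% return
  crossing lands at the programmed QT; an optional pressure channel has
  per-cycle maxima equal to the programmed systolic values.
* `sim_group_data()` draws the factorial table from programmed effect
  differences with Gaussian residuals.

What the generators do *not* emulate — and hence what passing tests do
not establish about real recordings — includes: baseline wander,
electrode motion and mains interference; P/T morphology variants and
genuine ectopy (screening is tested only against programmed outliers);
respiration as a physical channel (HF modulation is a pure sinusoid);
non-stationarity of autonomic tone within a segment; and realistic
pressure-waveform morphology beyond the per-cycle maximum.

## Numerical choices and problem sizes

Tolerances mirror each quantity's precision: spectral and ANOVA oracles
at 1e-8 relative; exact algebraic identities at machine precision; QT
recovery within 2 ms (half the T-kernel width step); recovery of
programmed band powers within 10% median relative error — the residual
bias is the white RR-noise floor spread across the band, which at the
default 1 ms noise contributes ≈ 8% of the HF target and is part of the
simulated conditions, not removed. Degenerate inputs are defined, not
exceptional: constant tachograms yield an all-zero spectrum; an empty
sequence list yields an absent gain, flagged; a flat ECG yields zero
peaks with a warning.

Test and validation runs are sized for speed while remaining in the
regime the method targets: tachograms of 180 s (~1500 beats) for
spectral recovery, 60–80 s for baroreflex recovery (50 seeds), 40–60
beats at 4 kHz for the ECG round trip, 1000 replicates for ANOVA
calibration. Full-length 15-minute sessions run through the identical
code path.

## Known limitations

The R-peak detector is single-lead and amplitude-based; it is validated
on synthetic morphology, not on pathological ECGs. The Q-onset and T-end
rules are one defensible reading of the verbal definitions in the
murine ECG literature, where T-wave-end conventions genuinely differ
between laboratories. The baroreflex aggregation (unweighted, pooled)
and the Poincaré pair as "the" non-linear index are explicit
interpretations where the source method is underspecified. Group
statistics assume homoscedastic Gaussian residuals; no repeated-measures
structure is supported.
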