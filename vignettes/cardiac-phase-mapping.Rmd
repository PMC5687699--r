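---
title: "Cardiac-frequency phase mapping: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-frequency phase mapping: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cfphase)
```

This vignette documents the science inside `cfphase`: the signal model,
the phase conventions every result depends on, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, the numerical choices, and the package's known limitations.

## Signal model and phase conventions

All timing is expressed as phase in radians, normalised by the cardiac
period.  A real component written `cos(2*pi*f_c*t + theta)` carries
*phasor angle* `theta`; a component that peaks earlier ("leads") has the
larger phasor angle.  The analytic continuous wavelet transform used
throughout maps such a component to coefficients proportional to
`exp(1i*(2*pi*f_c*t + theta))`, so coefficient angles are instantaneous
phasor angles and conjugate products difference them:

* `cross_wavelet_phase(a, b)` returns `Arg(sum_band W_a * Conj(W_b))`,
  i.e. `theta_a - theta_b`.  Delaying `b` by `dt` *increases* the result
  by `2*pi*f_c*dt`.  This fixes the global sign convention: **positive
  cross-wavelet phase means the second argument lags.**
* The angiographic field `cf_angiogram()` multiplies the pixel transform
  by the conjugated reference transform, so a pixel *delayed* by `dt`
  relative to the reference carries angle `-2*pi*f_c*dt`.
* The dorsal-minus-ventral quantity reported by `dorsoventral_phase()`
  and `dorsoventral_csf_phase()` is an *arrival-lag* difference: the
  dorsal zone's lag minus the ventral zone's.  It is computed as
  `Arg(V_ventral * Conj(V_dorsal))` (phasor angles and arrival lags have
  opposite signs), so that **a positive value means the wave reaches the
  ventral zone first and travels ventral-to-dorsal**.  The same holds
  for CSF pressure, where the per-record relative phase is the lag of
  CSF pressure behind the cardiac reference (ECG or ABP).

These conventions are pinned by tests: the delay-composition law on a
lag grid, exact antisymmetry under argument/zone/site swaps, and
end-to-end recovery of generator ground truth with the configured signs.

## The two wavelets and the cross product

Two variants of the analytic Gabor/Morlet wavelet
`psi(t) ~ (exp(1i*w0*t) - exp(-w0^2/2)) * exp(-t^2/2)` are used:

* `w0 = 6` — high frequency resolution; the default for 1-D filtering
  (`cf_filter()`), cross-wavelet phase, and the *reference* transform in
  angiography;
* `w0 = 1` — high temporal resolution; the *pixel* transform in
  angiography, able to follow the rapidly evolving angiographic signal.

Both are evaluated on a shared frequency grid (a `cf_band()`), each at
its own scale for a given pseudo-frequency, which makes the bin-by-bin
cross product well-posed.  Two numerical points matter:

* **Analyticity.**  The kernels are restricted to positive frequencies.
  The zero-mean correction term alone would give the `w0 = 1` wavelet a
  substantial negative-frequency response (its correction Gaussian is
  symmetric), creating a counter-rotating component that contaminates
  phases by ~0.25 rad.  The corrected form is exactly zero at DC, so
  admissibility is unaffected by the restriction.
* **A spectral gate on the pixel transform.**  The `w0 = 1` wavelet is
  broadband enough to leak the bolus envelope's low-frequency content
  into the cardiac scales, where it beats against the reference.
  `cf_angiogram()` therefore zeroes the pixel kernel below `0.4*f_c`
  with a cosine ramp ending at `0.75*f_c`; the cardiac band itself is
  untouched, so stationary CF phasors are unaffected.

The motion-referenced ("Eq 2") mode replaces the global signal `C` by
the pulse-motion chronometer `M` as the conjugated reference.  Written
as a triple product `W1[c] * Conj(W6[C]) * W6[M]` the field would retain
a rotating CF carrier, and interval averages of a rotating phasor vanish
— so the package uses the conjugate-reference form `W1[c] * Conj(W6[M])`,
which yields the stationary phasor whose angle is the pixel-vs-motion CF
phase that the arterial/venous and dorsoventral comparisons consume.
The invariant connecting the two modes is preserved and tested:
switching the reference shifts all pixel phases by one common angle.

**Inverse reconstruction.**  `cf_filter()` reconstructs by the linear
delta method (band sum of coefficients over `sqrt(scale)`), calibrated
by the analytically known band gain so that the real part reproduces the
in-band signal; verified to 0.2% for tones and 2% for band-limited
mixtures at interior samples.

**Cone of influence.**  Samples within one e-folding time
(`sqrt(2) * scale`) of either record edge at the band's largest scale
are flagged invalid and excluded from pooled statistics; the same margin
keeps the arterial/venous intervals away from the record edges.

## Locating the cardiac frequency

`select_cardiac_scale()` scans 0.5–5 Hz (half-octave margins, 12 voices
per octave), integrating wavelet power over the cone-of-influence-valid
samples of the *first-differenced* reference.  Differencing prewhitens:
the bolus envelope contributes a monotone low-frequency background with
no interior local maximum, while the cardiac bump survives.  A peak is
accepted when it is an interior local maximum exceeding 2.5x the higher
of its flanking power troughs; otherwise the function errors and asks
for an explicit `f_hint` — white noise and flat channels never
auto-select.  The returned band is one octave wide (+/- half an octave),
wide enough to tolerate the one-voice quantisation of the centre and
narrow enough to exclude respiratory and first-harmonic energy.

## The peri-ventricular band

The traced contour is resampled by arc length into 30 equal segments
(equal within 0.5%), preserving the one-to-one correspondence between
position along the ventricular perimeter and row index of the unfolded
profile.  The band offsets the contour by `thickness` along averaged
vertex normals into contiguous quadrilaterals; the default thickness is
one segment length.  That choice is acknowledged as arbitrary — it is a
plain parameter, and the rotation-invariance and recovery tests pass
across a range of values.  Zone labels follow the segment layout:
ventral = outer thirds (segments 1–10 and 21–30), dorsal = middle third
(11–20).

Pixel membership is pixel-centre-in-polygon with boundary ties resolved
deterministically to the lower polygon index; `band_signal()` takes the
complex *mean* (not sum) per polygon because polygon areas are unequal.
It matches a brute-force half-plane membership computation exactly in
tests.

`dorsoventral_phase()` pools the per-time zone phase difference only
where both zone magnitudes exceed half their 90th percentile: bolus
onset and washout samples carry envelope-leakage phase (correlated
across zones, difference near zero) rather than pulse-wave phase, and
would dilute the pooled mean toward zero.

## Arterial and venous intervals

The time-intensity curve (TIC) is the mean raw intensity over the band,
smoothed over one cardiac period.  The arterial interval is 5 beats of
inflow ending at the smoothed-TIC peak; the venous interval is 5 beats
starting 6 beats *after* the peak.  The venous guard gap reflects bolus
kinetics: for the first couple of seconds after the peak the decaying
arterial first pass still dominates the dispersed, slowly building
venous outflow, and interval averages taken there would mix the
compartments.  With the gap, each interval is >80% dominated by its own
compartment's envelope (asserted against generator ground truth), and
the configured +/-0.5 rad offsets are recovered within 0.05 rad.
`av_phase()` averages the motion-referenced complex band series over
each interval per polygon and takes phases, giving two 30-angle circular
samples compared by Watson's two-sample test.

## CSF pressure pipeline

The Lateral (dorsal) and Third (ventral) Ventricle epochs are recorded
minutes apart, so per-time samples cannot be paired.  Each record's CSF
pressure is referenced to its own concurrent ECG (or ABP) by
cross-wavelet phase — the lag of pressure behind the cardiac reference —
and one value is taken per detected cardiac cycle (circular mean of the
valid samples within the beat).  All dorsal-beat minus ventral-beat
differences are pooled; this is order-free, and shifting either epoch by
whole cardiac periods changes the pooled mean by <0.05 rad (tested).
The respiratory component is left in place and rejected by the cardiac
band filter.

The reported test is a Watson-style large-sample test of the pooled mean
direction against zero in its *two-epoch* form: the variance of a
difference of two mean directions, `delta_d/n_d + delta_v/n_v`, with
each record's circular dispersion taken over an AR(1)-adjusted effective
beat count (adjacent beats are positively correlated through the wavelet
smoothing time and the respiratory cycle).  The naive one-sample test on
the pooled all-pairs sample treats ~n^2 dependent differences as
independent and over-rejects drastically under the null (measured 18/20
at alpha = 0.05; the two-epoch form is calibrated, 2/40).

Clock alignment (`align_clocks()`) detects the single finger-flick
transient in each trace as the run of samples exceeding
`median + 8 * MAD`, merges candidates closer than 1 s, refuses to pick
silently when zero or several remain, and takes the onset as the
interpolated first crossing of half the peak excursion.  Accuracy is
about one video frame: over 100 random offsets in +/-5 s the maximum
error is ~0.023 s at 30 Hz video.

## Circular statistics

`circ_summary()` uses the resultant vector (`sd = sqrt(-2*log(Rbar))`).
`watson_one_sample()` is the large-sample mean-direction test (deviation
of the mean direction standardised by the circular dispersion
`(1 - rho2)/(2*Rbar^2)`), chosen because the scientific question is
about the *mean* being zero, which a goodness-of-fit statistic does not
address; its null p-values are uniform (KS over 2000 replicates) and it
agrees with a bootstrap-of-mean oracle within a factor of 3.
`watson_two_sample()` computes U2 on pooled ranks with tied blocks
collapsed (identical samples give exactly U2 = 0) and takes its p-value
from seeded random permutations (default 10^4), valid at the n = 30
polygon-sample scale; the asymptotic value is reported alongside.  Its
empirical size at alpha = 0.05 is 0.05 over 1000 null replicates.

`angular_qq()` centres each sample on its own circular mean before
matching quantiles, because raw angular quantiles depend on an arbitrary
cut point; the centring convention is recorded in the output.  For
equal-shape samples the *bulk* quantiles agree (mean absolute deviation
well under 0.15 rad at n = 200); the extreme quantiles of a concentrated
circular sample are order-statistic noise and are not a stable summary.

## What the synthetic generator emulates

`generate_cine()` builds: a gamma-variate first-pass bolus
(`alpha = 6`, `beta = 1/3` s: a ~2 s rise and fast washout, peaking just
before mid-recording); a venous copy delayed by five cardiac periods
(2 s at the default 2.5 Hz — the cerebral arteriovenous transit scale)
and dispersed 2x with 0.85 amplitude, keeping the combined TIC
single-peaked; CF modulation at depth 0.2 with per-compartment phasor
offsets relative to the pulse-motion phase; a ventral-to-dorsal phase
profile along the contour (zone plateaus with 2-segment linear
transitions, scaled so the configured gradient equals the ventral-vs-
dorsal zone-mean contrast exactly); an oscillating Gaussian blob
(amplitude 0.4 px) as the trackable motion object; and additive Gaussian
noise (default SD 2 intensity units against a bolus amplitude of 100).
Heart rates default to 2.5 Hz for the piglet-like cine and 1.2 Hz for
the human-like physiology — anesthetised piglets and adult humans
respectively; both are plain parameters.

`generate_physio()` produces two-epoch CSF pressure (baseline +
respiratory sinusoid + CF component with the configured inter-site lag +
noise) with a shared cardiac clock driving a Gaussian-pulse-train ECG
and a sinusoidal ABP; epochs start minutes apart so cardiac
synchronization is genuinely exercised.  `generate_flick_pair()` adds a
step-plus-decay motion transient and a sharp pressure spike at a known
clock offset over CF background.

Not emulated: ultrasound speckle and acoustic physics, endoscope optics,
vessel geometry (compartments are half-bands of the contour),
respiration-gated imaging artifacts, heart-rate variability, and ECG
morphology beyond an impulse train.  Passing recovery tests therefore
demonstrates that the *analysis chain* is correct and unbiased under
controlled conditions — not that real ultrasound or endoscopy data meet
those conditions; on real data, operator choices (contour tracing, ROI
selection) and physiological nonstationarity will dominate the error
budget.

## Problem sizes and determinism

The test suite validates the full-size study condition (128 x 128 px,
30 Hz, 20 s, 10 seeds) for the dorsoventral recovery, and a 64 x 64 px,
12 s cine for the gradient sweep (-pi/2 ... pi/2, 3 seeds each); the
statistical calibrations use 1000–2000 replicates.  The acceptance
script pools 3 seeds per headline quantity at the full acquisition
scale.  Every random quantity is seeded; the same seed reproduces the
same data bit for bit (the generators save and restore the caller's RNG
state).

## Known limitations

* The per-pixel transform assumes uniform sampling; gaps must be
  interpolated before analysis (the loader does this and flags the
  samples).
* Rigid-translation tracking measures a single region's net motion; it
  cannot resolve distributed wall deformation, and its ROI must enclose
  the tracked object with quiet background at the boundary (a taper
  window would bias the sub-pixel scale low, so a sharp polygon mask is
  used instead).
* The dorsoventral phase is a two-zone summary; it does not estimate a
  propagation velocity.
* Arterial/venous separation relies on bolus kinetics providing
  compartment-dominant intervals; with heavily overlapping envelopes the
  interval averages mix compartments and bias both phases toward each
  other — visible in the generator when the transit delay is made small.
* Watson p-values are floored at 1e-16; permutation p-values cannot fall
  below `1/(B+1)`.
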