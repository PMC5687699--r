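# cfphase

Cardiac-frequency phase mapping of vascular pulse waves and CSF pressure
around the brain ventricles, by complex cross-wavelet angiography.

## The problem

Every heartbeat drives a vascular pulse wave (PW) through the brain and a
pressure wave through the cerebrospinal fluid (CSF) in the ventricles.
Whether these waves share a consistent spatial phase pattern over the
ventricular surfaces — for example, arriving at the ventral surface
before the dorsal one — is a question about *timing within the cardiac
cycle*, best expressed as a phase in radians after normalising by the
cardiac period.  `cfphase` provides the full analysis chain for asking
that question of two kinds of data:

* **contrast-bolus cine angiography** (e.g. cranial-window ultrasound):
  every pixel is a time signal; its cardiac-frequency (CF) state is
  extracted by a cross-wavelet product and referenced either to the
  global angiographic signal or to a tracked brain-pulse-motion
  chronometer;
* **intraventricular CSF pressure recordings** made at two sites minutes
  apart, synchronized through a concurrent ECG/ABP cardiac reference and
  aligned to video by a deliberate "finger-flick" catheter transient.

The package is aimed at researchers analysing cardiac-gated cine or
pressure data who need per-pixel CF phase, region-based phase profiles
along a traced anatomical contour, and circular statistics for the
resulting angle samples.

## The method in brief

For a pixel signal `c_ij(t)` and a reference signal `r(t)` (the global
spatial mean `C`, or the pulse-motion signal `M`), both are transformed
with analytic Gabor/Morlet wavelets — the pixel with the
high-temporal-resolution variant (centre parameter 1), the reference with
the high-frequency-resolution variant (centre parameter 6) — on a shared
frequency grid around the cardiac frequency.  The per-pixel CF state is
the band sum of the cross product

    x_ij(t) = sum_s  W1[c_ij](s, t) * Conj( W6[r](s, t) )

whose magnitude maps PW strength and whose angle is the pixel's CF phase
relative to the reference (a pixel delayed by `dt` carries angle
`-2*pi*f_c*dt`).  A traced ventricular contour is divided into 30
equal-arc-length segments and offset outward into a band of contiguous
quadrilaterals; the complex mean per polygon gives a `30 x T` band series
that unfolds the ventricular surface into a space-time phase profile.
Dorsal (middle third) and ventral (outer thirds) zone signals are
compared through the angle of their conjugate product; arterial and
venous phases come from interval averages before and after the
time-intensity-curve peak.  Two-site CSF pressure epochs are compared by
per-beat cross-wavelet phase lags behind the cardiac reference.  All
angle samples are summarised with circular means/SDs, Watson one- and
two-sample tests, rose diagrams and angular Q-Q plots.

A synthetic-data generator (`generate_cine()`, `generate_physio()`,
`generate_flick_pair()`) produces inputs with known ground-truth phase
structure, so the whole chain is validated end-to-end by parameter
recovery.

## Worked example

```r
library(cfphase)

# synthetic piglet-like acquisition: 128x128 px, 30 Hz, 20 s, heart rate
# 2.5 Hz, ventral zone leading the dorsal zone by 0.7 rad
sim <- generate_cine(dim = c(128, 128), fs = 30, duration = 20,
                     cardiac_freq = 2.5, ventral_dorsal_gradient = 0.7,
                     seed = 42)
fit <- periventricular_analysis(sim$cine, sim$truth$contour, sim$blob_roi)
fit

# two-epoch CSF pressure with the ventral site leading by 0.8 rad
phys <- generate_physio(site_phase_lag = 0.8, seed = 42)
dorsoventral_csf_phase(phys$dorsal, phys$ventral)
```

prints

```
Peri-ventricular CF pulse-wave phase analysis
  cardiac frequency: 2.520 Hz
  pulse motion axis: (1.00, -0.00), 100% variance
Dorsal-minus-ventral CF pulse-wave phase
  pooled mean 0.698 rad, sd 0.009 rad over 190 valid samples
  Watson one-sample test vs 0 rad: p <2e-16
  (positive: the wave reaches the ventral zone first)
Arterial vs venous pulse-wave phase (relative to brain pulse motion)
  arterial: mean 0.246 rad, sd 0.335 rad (n = 30)
  venous:   mean -0.720 rad, sd 0.338 rad (n = 30)
  Watson two-sample U2 = 1.2528, permutation p 1e-04

Dorsal-minus-ventral CF phase of CSF pressure (ecg-referenced)
  21 dorsal x 22 ventral beats -> 462 pooled differences
  pooled mean 0.798 rad, sd 0.026 rad
  Watson one-sample test vs 0 rad: p <2e-16
  (positive: ventral CSF pressure peaks first)
```

The pooled dorsoventral mean recovers the injected 0.7 rad ventral lead;
the CSF pipeline recovers the 0.8 rad inter-site lag; the cardiac
frequency is located automatically from the global angiographic signal;
and the arterial/venous phases (configured at +0.5/-0.5 rad relative to
pulse motion; here shifted by the nonzero spatial gradient's band
average) separate decisively under Watson's two-sample test.  Note the
positive sign convention throughout: a positive dorsal-minus-ventral
phase means the wave reaches the ventral zone first, i.e. travels from
ventral to dorsal.

Rendering helpers: `plot()` on the band series draws the unfolded
brightness-hue PW profile, `plot(circ_hist(...))` the rose diagram,
`plot(angular_qq(...))` the angular Q-Q plot and `render_scattergram()`
the magnified wall-motion scattergram.

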