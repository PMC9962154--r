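---
title: "veinscan: models, timing analysis and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{veinscan: models, timing analysis and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the optical and
camera models, the timing analysis that fixes the defaults, the
demultiplexing algorithm's degenerate cases, the pulse estimator, and
what the simulation does and does not establish about real data.

## 1. The finger phantom

The phantom is a deliberately simple, closed-form optical model chosen
for testability, not a radiative-transfer simulation.

**Back-lit (trans-illumination) rendering.** Per pixel, the irradiance
reaching the sensor from a lit diode is Beer–Lambert attenuation with a
separable source falloff:

$$ I(\mathbf{p}, t) = P \cdot G_\sigma(\mathbf{p} - \mathbf{p}_d)
   \cdot \exp\!\big[-\mu_t(\lambda) T(\mathbf{p})
   - \mu_b(\lambda) V(\mathbf{p}) (1 + a\, w(t))\big] $$

where $P$ is the diode's relative power, $G_\sigma$ a Gaussian falloff
kernel (diffuse transmission through tissue blurs point sources; width
$\sigma$ defaults to 0.35 × frame height), $T$ and $V$ are per-pixel
bulk-tissue and vein-blood path lengths (arbitrary length units), and
$\mu_t, \mu_b$ absorption coefficients per wavelength. Nail pixels use
a reduced tissue depth (factor 0.45), reproducing the bright nail and
lunula regions of trans-illuminated fingers. Multiple lit diodes add
linearly.

**Cardiac modulation.** $w(t)$ is a zero-mean waveform — fundamental
sinusoid plus a 0.3-weighted second harmonic, normalized to unit peak —
giving the asymmetric rise/fall of a blood-pressure pulse. The
amplitude parameter $a$ modulates the *vein path length*; the resulting
fractional intensity modulation at a vein pixel is
$\approx 2\mu_b V a$ peak-to-peak, i.e. the observed brightness
modulation is the configured amplitude scaled by the local vein optical
depth. Intensity modulation of transmitted light is a few percent at
the default $a = 0.03$, as expected for photoplethysmography. Default
rate is 90 beats/min.

**Absorption defaults.** The device's wavelengths are 940 nm (140 mW),
875 nm (210 mW) and 730 nm (240 mW) for the three back-light rows, plus
an 830 nm external front LED. Published tissue optics do not pin down
effective per-pixel path-length coefficients for this geometry, so the
defaults (`default_absorption()`) are *illustrative*: chosen once so
that vein contrast is visible at all three wavelengths and strictly
ordered (strongest at 940 nm). Tests assert only orderings, never the
absolute values.

**Front-lit rendering** is external power × falloff × a multiplicative
surface-texture map inside the finger silhouette. Veins are sub-surface
and do not appear: `render_frontlit()` is exactly invariant to the vein
map, which the tests check both exactly and as a near-zero correlation
between texture and vein structure.

**Procedural generation** (`generate_phantom()`) draws a capsule
silhouette with a dome thickness profile, a branching vein network from
seeded random walks (vessel radii 1–4 px, i.e. widths 2–8 px), a
nail/lunula ellipse and a smoothed random texture field; everything is
deterministic for a fixed seed.

What the phantom does **not** emulate: scattering point-spread beyond
the falloff kernel, 3D geometry and refraction, finger motion, ambient
light gradients over time, sensor fixed-pattern noise. Consequently,
passing tests demonstrate the correctness of the *protocol and
algorithms* under ideal optics, not robustness to motion or to
realistic skin optics.

## 2. The acquisition protocol and camera model

**Timing.** Each illumination cycle is: register update `t_u` → delay
`t_delay = 3 ms` (all LEDs off for `t_off = t_u + t_delay`, which
provides the dark reference frames) → LEDs of pattern P on → after
`seg_lag` the 7-segment indicator shows the pattern code → both stay on
for `t_on = 10 ms` → indicator off → after another `seg_lag` LEDs off.
Twelve single-diode patterns P1–P12 are followed by P13, the external
front light with indicator sentinel `000011110000`.

**Camera.** Free-run rolling shutter: row $r$ of frame $k$ integrates
irradiance over $[k/f + r\rho,\; k/f + r\rho + E]$ with frame rate
$f = 130$/s, exposure $E = 5$ ms, and row readout $\rho = 1/(f \cdot
\mathrm{rows})$; the integral is scaled by a gain (default 40000 ADU
per irradiance-second: unit irradiance over a full exposure reads
200 ADU), floored to integer and clipped at 255. Frame timestamps
depend only on the frame rate — there is no synchronization with the
illuminator. A 10<sup>-6</sup> ADU guard is added before flooring so
integrals sitting on an integer up to floating-point error quantize
stably.

**Timing analysis behind the defaults.** Three windows interact with
the camera's 12.7 ms full-frame exposure span
($(\mathrm{rows}-1)\rho + E \approx 7.7 + 5$ ms):

* *Image completeness.* The per-pixel maximum over a window's frames
  recovers a fully lit value for row $r$ only if some frame's row-$r$
  exposure lies entirely inside the LED window. Since candidate
  exposures recur every $1/f = 7.69$ ms, this is guaranteed for every
  row exactly when the LED window is at least $E + 1/f = 12.7$ ms.
  A bare 10 ms window fails this and leaves ~5–8% rms brightness
  artifacts on extracted images — enough to bury a few-percent pulse.
  The indicator is switched through an I/O expander with
  millisecond-scale transaction latency, so the LEDs are lit before and
  after the 10 ms both-on window; the default `seg_lag = 1.5 ms` makes
  the LED window 13 ms and restores the guarantee.
* *Cycle budget.* `t_u` is hardware-determined and not a printed
  constant; the default 14 ms makes the cycle
  `t_u + t_delay + 2·seg_lag + t_on = 30 ms`, which at 13 patterns per
  sweep reproduces the device's throughput of ~33 useful frames per
  second from ~130 FPS. `t_u` also carries truncated-Gaussian per-cycle
  jitter (default sd 1.5 ms, a realistic I2C + non-real-time-OS spread).
  Jitter matters beyond realism: the exact 30 ms / 7.692 ms
  commensurability would otherwise place a coherent sampling artifact
  at 3.3 Hz — inside the physiological band.
* *Background purity.* A guaranteed all-rows-dark frame would need an
  off-gap of $12.7 + 7.7 = 20.4$ ms; the 30 ms cycle cannot afford that
  alongside a 13 ms LED window, so frames that straddle an LED switch
  edge can read dark on the detectors while their extreme rows carry
  some finger light. The extraction therefore uses the *darkest* frame
  of each delimiter run as background (Section 3), which confines any
  residual contamination to roughly the outer 20% of rows at top or
  bottom; the default ROI sits in the central 25–75% of rows.

The indicator strip occupies the columns beyond the finger region, as a
longitudinal extension of the fingertip. Its display module sits in an
opaque case: the simulator blanks finger back- and front-light in those
columns, otherwise unattenuated light passing around the finger would
flood the detector pixels. Indicator sites are modeled as single
pixels — the extraction algorithm never reads anything else — at a
saturating irradiance (≥ 255 ADU over a full exposure).

## 3. Demultiplexing

Per frame, the twelve detector levels are referenced to a per-site
baseline (the minimum over the video) and thresholded at 20 ADU with
`>=` (a level exactly at the threshold counts as lit; the low threshold
deliberately catches diodes lit for only a fraction of the exposure).
With noise-free dark frames the baseline is zero and this is the plain
absolute rule; the referencing makes classification — and hence window
segmentation — invariant to constant stray light even beyond the
threshold value.

Dark frames delimit windows. Within a window the consensus code is the
code of the frame with the largest total detector sum (the
best-exposed frame; ties go to the earliest), frames with a different
code (rolling-shutter transition frames) are excluded, the rest combine
by per-pixel maximum, and the darkest frame of the preceding dark run
is subtracted with clipping at 0. One image, one time (timestamp of
the first contributing frame) and one code are emitted per window.
Degenerate inputs: a video with no dark frame cannot establish
delimiters or background and errors; an all-dark video errors; windows
before the first dark frame and a trailing unclosed window are dropped
and counted in the result's `dropped` attribute.

Stray-light invariance holds wherever information survives clipping:
pixels already at 255 (lit indicator segments by construction) cannot
be invariant to an additive offset, so the invariance contract — and
its test — applies to unsaturated pixels.

## 4. Pulse extraction

`roi_mean_series()` averages each extracted image over a rectangular
ROI (0-based, half-open; a required input — the device analogue is an
arbitrary patch chosen inside the finger area). External-light frames
carry no vein signal and are excluded by default.
`normalize_combine()` divides each diode's series by its own mean
(each subset then has mean exactly 1, to within 1e-9) and merges all
samples time-ordered; the normalization makes the combination invariant
to any per-diode rescaling, which the tests assert exactly.

`estimate_pulse_rate()` is this package's addition (the device work
only plots the combined signal): a least-squares single-sinusoid fit on
a frequency grid over 0.6–3.5 Hz (36–210 bpm), grid step
$1/(8\,\mathrm{span})$, peak refined by golden-section search; the
amplitude is the fitted sinusoid amplitude (half peak-to-peak) on the
unit-mean scale. Before fitting, samples further than 4 median absolute
deviations from the median are discarded: windows that catch only a
partial exposure leave occasional gross brightness outliers, the
image-series analogue of motion artifacts in photoplethysmography.
A pulse is declared only if the peak amplitude reaches `min_amplitude`
(default 0.001) *and* stands `min_peak_ratio` (default 4) above the
median spectral amplitude over the band. The absolute gate was
calibrated on simulated pulseless acquisitions, whose largest spectral
peaks stay near 0.0003 under the default conditions, while a faint
amplitude-0.01 phantom yields at least ~0.0015; 0.001 sits between the
two with a ~3× safety factor over the null. The estimator requires at
least three cardiac periods at the low band edge (5 s of signal) and
otherwise errors. Per-diode linear detrending is available but off by
default.

## 5. Problem sizes and reproducibility

Tests and the acceptance script scale the *pixel count* down, never the
timing: the rolling-shutter phenomena depend on frame rate, exposure
and row-readout ratio, not on how many pixels are simulated. The test
suite uses 64 × 96 frames (with 128 × 192 where texture statistics need
more independent patches) and recordings between 63 frames (one sweep)
and 3900 frames (30 s) for end-to-end pulse recovery at 50/90/150
beats/min. The acceptance script runs the full 260 × 336 slice: 676
frames (5.2 s) for the extraction-yield measurement and 63 frames for
the one-sweep pattern count. All randomness (phantom generation, timing
jitter, optional read noise) flows from a single integer seed, and
noise-free runs are bit-reproducible.

## 6. Known limitations

* The optical model is closed-form; absolute brightness and contrast
  values are not physiological, and only orderings and invariances are
  meaningful.
* The background mechanism cannot be made exact within a 30 ms cycle
  (Section 2); residual edge-row artifacts survive at the few-ADU level
  and motivate both the darkest-delimiter rule and the central ROI
  default.
* The pulse detection gates were calibrated on this simulator's noise
  under default conditions; real recordings with motion or ambient
  flicker will need the gates revisited against measured null
  distributions.
* A pulse faster than ~200 bpm aliases against the upper band edge and
  is out of scope, as are waveform morphology, oxygen saturation and
  heart-rate variability.
* Multi-diode illumination codes are supported throughout, but the
  device's P1–P12 are single-diode; file naming for other non-external
  codes (`P<code>_<t>.png`) is an extension beyond the dataset
  conventions.
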