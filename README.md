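# veinscan

Software pipeline of a multi-wavelength near-infrared (NIR) finger-vein
acquisition device, for researchers working on finger-vasculature
biometrics and liveness detection who need the device's data path —
illumination protocol, free-run rolling-shutter capture, frame
demultiplexing and pulse extraction — as testable, reproducible code
without the hardware.

## The problem and the method

A trans-illuminated finger is imaged by a free-running rolling-shutter
camera (~130 frames/s, 5 ms exposure, 260-pixel slice) while twelve
back-light NIR diodes (three wavelength rows: 940, 875, 730 nm) and one
external 830 nm front light cycle through 13 illumination patterns
P1–P13. The camera is *not* synchronized with the illuminator: instead,
a 7-segment display in the field of view encodes the current diode
state, and a timing protocol (register update `t_u` → delay
`t_delay = 3 ms` → LEDs on → indicator on for `t_on = 10 ms` → indicator
off → LEDs off) guarantees that every cycle is recoverable after the
fact.

Demultiplexing reads twelve fixed *detector pixels* d<sub>j</sub>(i) in
the indicator region of every frame i and thresholds them at 20 ADU
(saturation 255 ADU): a frame with all detectors dark is a reference
(background) frame that delimits illumination windows; within a window,
all frames sharing the window's code are combined by per-pixel maximum —
so rows that a rolling-shutter transition caught only partially lit are
overridden by fully lit ones — and the darkest delimiter frame B is
subtracted, cancelling constant stray light. The result is three
parallel buffers: images `Iextracted`, times `Textracted`, and diode
state codes `DSextracted` (the external-light frames carry the sentinel
code `000011110000`), written to disk as `D01_0.51.png`, …,
`DEXT_0.39.png` in a `_processed` directory.

The blood pulse is recovered from the demultiplexed series: mean
brightness over a rectangular ROI in the finger, normalized per diode to
mean 1 (so diodes of different power and wavelength combine), and fitted
with a least-squares periodogram over the physiological band
0.6–3.5 Hz. With n multiplexed diodes and heart rate f, the overall
sampling rate must reach 2·(f/60)·n samples/s (36 samples/s at 90 bpm
and 12 diodes) — which the 13-pattern, 30 ms-cycle protocol meets at
~33 extracted frames/s. A phantom with no cardiac modulation yields
"no pulse detected": the liveness safeguard against artificial fingers.

Because no hardware is required, the package includes a procedural
finger phantom (Beer–Lambert optics: per-pixel tissue and vein-blood
path lengths, wavelength-dependent absorption, nail/lunula relief,
surface texture for front-lit rendering, and a configurable cardiac
modulation of the vein path length) and a rolling-shutter camera model
(per-row integrate-and-dump, gain, 8-bit quantization, optional read
noise), so every stage is testable end to end.

## Worked example

Simulate 30 s of acquisition on a reduced 64 × 96 frame (the timing
physics only depend on frame rate and exposure, not pixel count),
demultiplex it, and estimate the pulse:

```r
library(veinscan)

cfg <- default_config()
cfg$geometry <- list(rows = 64L, cols = 96L, finger_col_frac = 0.82)
cfg$n_frames <- 3900L   # 30 s at 130 frames/s
cfg$seed <- 7L
cfg <- resolve_config(cfg)

report <- run_end_to_end(cfg)
report
#> run_report (seed 7):
#>   frames captured:  3900 (30.00 s)
#>   frames extracted: 999 (33.3 /s)
#>   distinct codes:   13
#>   pulse_estimate: 1.50 Hz (90 bpm), amplitude 0.008 (peak ratio 41.5)
```

Reading the output: 3900 raw frames become 999 clean per-diode images —
33.3 useful frames per second, one per 30 ms illumination cycle — with
all 13 pattern codes (P1–P12 plus the external sentinel) recovered. The
phantom's configured 90 bpm pulse is found at 1.50 Hz; the fitted
fractional amplitude (0.8% of mean brightness) is the configured 3%
vein-path modulation attenuated by the ROI's mix of vein and non-vein
pixels.

The same stages are exposed individually (`simulate_acquisition()`,
`extract()`, `roi_mean_series()`, `normalize_combine()`,
`estimate_pulse_rate()`, `write_processed()`, `read_frames()`), and as a
command-line tool installed under `exec/`:

```sh
veinscan simulate --config cfg.yaml --out raw/
veinscan extract  --in raw/ --config cfg.yaml --out finger01
veinscan pulse    --in finger01_processed --roi 16,20,32,30 --out pulse.csv
veinscan run      --config cfg.yaml
```

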