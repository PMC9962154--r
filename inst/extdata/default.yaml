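# Default acquisition/extraction configuration.
# Any omitted key falls back to the documented package default
# (see ?default_config); this file spells out the main ones.
seed: 1
n_frames: 1000
geometry:
  rows: 260          # post-binning slice height
  cols: 336
  finger_col_frac: 0.82
timing:
  t_u: 0.014         # register update (hardware-determined; jittered)
  t_delay: 0.003
  t_on: 0.010        # LEDs + 7-segment both on
  exposure: 0.005
  frame_rate: 130
  seg_lag: 0.0015
  t_u_jitter_sd: 0.0015
camera:
  gain: 40000        # ADU per irradiance-second
  read_noise_sd: 0
detector:
  threshold: 20      # ADU
  saturation: 255
phantom:
  vein_density: 1.0
  pulse:
    rate_bpm: 90
    amplitude: 0.03
    phase: 0
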