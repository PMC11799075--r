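# Default experiment configuration (schema version 1).
# Every value shown equals the packaged default; a user config may state
# only the fields it changes.
schema: 1
n_histories: 20000
max_scatters: 2
min_counts: 10000      # observed main-window counts before recording stops
min_seconds: 5         # per-second statistics need several seconds
eta: 1.4               # window-fraction exponent for scaling predictions
injected_activity_bq: 7.4e9
tfp_density_g_cm3: 3.4 # tungsten functional paper bulk density (not a
                       # settled literature value; override if known)
filters: [none, tfp, lead]
detector:
  tau_full_us: 0.5     # full-window paralyzable dead time
  resolution_fwhm: 0.094   # fractional FWHM at 208.4 keV
  pileup: true
  full_window: [20, 400]   # keV
tew:
  subwidth_frac: 0.10
  basis: photopeak     # "10%" of the photopeak energy (alt: "window")
organs:                # synthetic organ split; only the 52 %IA total is
                       # anchored to published patient conditions
  - {name: liver,        shape: box,       center: [-5, 3.5, 8],  half_size: [8, 5, 6],     percent_ia: 36}
  - {name: spleen,       shape: box,       center: [9, -4, 6],    half_size: [4, 2.5, 4],   percent_ia: 6}
  - {name: kidney_left,  shape: ellipsoid, center: [6, -5, -2],   half_size: [2.5, 2, 4.5], percent_ia: 5}
  - {name: kidney_right, shape: ellipsoid, center: [-6, -5, -2],  half_size: [2.5, 2, 4.5], percent_ia: 5}
retention:
  kind: monoexp
  half_life_h: 80      # synthetic slow-excretion effective half-life
  anchor: [24, 0.52]   # 52 %IA retained at 24 h
time_grid: {from: 24, to: 120, by: 8}
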