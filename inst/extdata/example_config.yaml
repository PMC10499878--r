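# Example nanosipr pipeline configuration: four co-cultured strains
# spanning weak to strong incorporation, plus a killed control.
seed: 1
tau_ns: 44
register: true
max_shift_px: 2
alpha: 0.05
k_range: [1, 6]
cells_per_field: 25
algal_per_field: 1
generator:
  raster_um: 20
  pixels: 256
  cycles: 24
  dwell_ms: 1
substrate:
  f_s_C_labeled: 0.18      # measured 13C fraction of the added exudate
  f_s_N_labeled: 0.45      # measured 15N fraction
  dilution_unlabeled: 0.5  # unlabeled exudate released during incubation
  duration_days: 1
killed:
  n_bacteria: 25
  n_algal: 3
strains:
- name: strainA
  bact_C_daily: 0.010
  bact_N_daily: 0.005
  cd_C: 0.25
  cd_N: 0.25
  algal_C_daily: 0.002
  algal_N_daily: 0.001
  n_cells: 25
  cells_per_ml: 2.0e+6
- name: strainB
  bact_C_daily: 0.030
  bact_N_daily: 0.080
  cd_C: 0.30
  cd_N: 0.30
  algal_C_daily: 0.004
  algal_N_daily: 0.003
  n_cells: 25
  cells_per_ml: 4.0e+6
  attached_fraction: 0.1
- name: strainC
  bact_C_daily: 0.054
  bact_N_daily: 0.160
  cd_C: 0.35
  cd_N: 0.40
  algal_C_daily: 0.005
  algal_N_daily: 0.005
  n_cells: 25
  cells_per_ml: 2.0e+7
- name: strainD
  bact_C_daily: 0.009
  bact_N_daily: 0.004
  cd_C: 0.20
  cd_N: 0.20
  n_cells: 25
  cells_per_ml: 4.0e+5
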