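# Default run configuration: the emulated TLE/control study conditions.
cohort:
  n_patients: 18
  n_controls: 29
  age_mean: {patient: 30.4, control: 27.8}
  age_sd: {patient: 8.16, control: 5.78}
  male_count: {patient: 10, control: 17}
  duration_mean: 13.90
  duration_sd: 7.15
  onset_mean: 16.28
  onset_sd: 10.69
  duration_onset_r: -0.632
  viq_mean: {patient: 90.00, control: 109.45}
  viq_sd: {patient: 11.57, control: 11.91}
  piq_mean: {patient: 95.06, control: 109.00}
  piq_sd: {patient: 10.90, control: 10.51}
  affected_regions: [32, 33, 35, 36, 39, 40, 41, 81, 83, 85, 87, 89]
  iq_regions: [2, 21, 22, 54, 57, 66]
  fa_attenuation: 0.775
  duration_slope: 0.004
  iq_coupling: 0.04
  edge_noise_sd: 0.015
  density_calibration: 10.17
  dist_scale: 30
  hemi_boost: 1.25
  lobe_boost: 1.9
  kernel_sharpness: 3
  hub_regions: [4, 43, 51, 60, 67, 68, 73, 74, 85, 86, 90]
  hub_boost: 2.1
  fa_excess_mean: 0.12
network:
  fa_threshold: 0.2
  min_count: 1
metrics:
  weight_conversion: reciprocal
  n_null: 100
  swaps_per_edge: 10
  sd_multiplier: 1.0
statistics:
  q_level: 0.05
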