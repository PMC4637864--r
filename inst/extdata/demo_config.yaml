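simulation:
  genome: default
  marker_density: 2.0
  recomb_rate: 0.05
  sdp_share: 0.9
  n_strains: 60.0
  mice_per_strain_per_sex: 4.0
  architecture: default
  min_minor_strains: 2.0
  seed: 42.0
scan:
  model: linear
  sex_handling: covariate
  unit: animal
caller:
  min_run: 3.0
  gap_tolerance: 2.0
overlap:
  bin_width: 5000000.0
  n_perm: 1000.0
enrichment:
  mode: simulate
  n_genes: 2000.0
  n_list: 200.0
  spike: 30.0
  spike_window: 2000000.0
log_level: info
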