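# Null scenario: identical to the default study conditions but with every
# status and treatment effect multiplier equal, so dominants and
# subordinates differ only through body mass.
name: null_scenario
design:
  n_pairs: 16
  n_social_recovery: 9
  mass_meanlog: 2.140066  # log(8.5 g)
  mass_sdlog: 0.15
  pair_mass_ratio_sdlog: 0.05
  chamber_volume_l: 0.5
protocol:
  cycle_measure_min: 5
  cycle_flush_min: 5
  baseline_hours: 48
  n_baseline_blocks: 2
  recovery_hours: 6
  photoperiod_light_h: 13
  sunrise_ramp_min: 30
  chase_duration_min: 3
  air_exposure_min: 1
  sample_interval_s: 30
effects:
  allometric_coefficient: 10    # umol O2 h^-1 g^-b
  allometric_exponent: 0.8
  routine_level: 1
  circadian_night_fraction: 0.7
  mmr_multiplier: 6             # factorial aerobic scope of unaffected cells
  recovery_rate_k: 1.5          # h^-1, unaffected cells
  process_cv:
    pair: 0.05
    routine: 0.05
    mmr: 0.05
    k: 0.05
  trace_noise_sd: 0.15          # umol O2 L^-1 per reading
  o2_saturation_umol_l: 247     # 27 C freshwater
  fish_density_g_ml: 1
targets:
  mmr_deficit_social: 0
  as50_excess_social: 0
qc:
  r2_min: 0.90
  mixing_window_s: 30
  min_points: 3
  background_rate: 0
metrics:
  resting_n: 10
  routine_n: 5
  routine_delay_min: 30
  max_window_min: 60
  sustained_n: 1
  routine10_margin: 0.10
  as50_fraction: 0.5
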