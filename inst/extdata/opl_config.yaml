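seed: 1
calibrations:
  vehicle:
    half_life_h: 7.5
    flux_multiplier: 1.0
    phi: 0.4
    yield: 2.5
    green_ss: 1000.0
    k_green: 0.1540327
    red_bg: 50.0
    noise_cv: 0.064
    base_area: 0.35
    toxic: no
    toxicity_onset_h: 5.0
    toxicity_ramp_h: 5.0
    toxicity_floor: 0.4
    autofl_offset_green: 0.0
    autofl_offset_red: 0.0
    puncta_clustering: no
    clustering_rate: 0.0
  torin1:
    half_life_h: 7.5
    flux_multiplier: 3.0
    phi: 0.4
    yield: 2.5
    green_ss: 1000.0
    k_green: 0.1540327
    red_bg: 50.0
    noise_cv: 0.064
    base_area: 0.35
    toxic: no
    toxicity_onset_h: 5.0
    toxicity_ramp_h: 5.0
    toxicity_floor: 0.4
    autofl_offset_green: 0.0
    autofl_offset_red: 0.0
    puncta_clustering: no
    clustering_rate: 0.0
  bafilomycin:
    half_life_h: 7.5
    flux_multiplier: 0.0
    phi: 0.4
    yield: 2.5
    green_ss: 1000.0
    k_green: 0.1540327
    red_bg: 50.0
    noise_cv: 0.064
    base_area: 0.35
    toxic: no
    toxicity_onset_h: 5.0
    toxicity_ramp_h: 5.0
    toxicity_floor: 0.4
    autofl_offset_green: 0.0
    autofl_offset_red: 0.0
    puncta_clustering: yes
    clustering_rate: 0.02
  cortical:
    mean_half_life_h: 33.2
    sd_half_life_h: 8.0
    baseline_hazard: 0.0003
    hazard_beta: 0.05
    initial_intensity: 2000.0
    plateau: 700.0
    noise_cv: 0.05
    dead_floor: 10.0
    preconversion_h: -0.5
    observation_h: 168.0
    interval_h: 1.0
    opl_window_h: 36.0
  spinal:
    mean_half_life_h: 37.1
    sd_half_life_h: 8.0
    baseline_hazard: 0.0003
    hazard_beta: 0.05
    initial_intensity: 2000.0
    plateau: 700.0
    noise_cv: 0.05
    dead_floor: 10.0
    preconversion_h: -0.5
    observation_h: 168.0
    interval_h: 1.0
    opl_window_h: 36.0
analysis:
  readout_h: 9.0
  gfp_t1: 15.0
  hit_sd: 3.0
  rolling_ball_radius: 150.0
  coloc_overlap: 0.5
  death_threshold: 0.2
  death_persistence: 2.0
  spline_df: 4.0
  opl_window_h: 36.0
screen:
  n_compounds: 320.0
  n_enhancers: 6.0
  n_inhibitors: 10.0
  n_toxic: 3.0
  n_autofluorescent: 0.0
survival:
  enabled: no
  n_neurons: 200.0
  populations:
  - cortical
  - spinal
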