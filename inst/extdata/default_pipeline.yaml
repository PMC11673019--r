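seed: 101
cohort:
  n_control: 41
  n_kc_by_stage:
  - 2
  - 9
  - 3
  - 8
species_cohort:
  n_human: 20
  n_porcine: 20
  porcine_110_scale: 0.3
generator:
  noise_sd: 0.05
  height_jitter_sd: 0.05
  peak_width_hz: 10.0
  baseline_level: 2.0
  baseline_noise_sd: 0.02
calibration:
  a: 0.0651
  b: 233.1
  thickness_unit: um
  min_prominence: 0.05
ml:
  n_folds: 5
  n_repeats_svc: 20
  n_repeats_vbgmm: 1
  cost: 1.0
fem:
  enabled: yes
  n_elements: 1024
  iop_pa: 2000.0
  poisson_ratio: 0.42
  density_g_cm3: 1.038
  healthy:
    elastic_modulus_mpa: 3.1
    central_thickness_um: 550.0
    peripheral_thickness_um: 700.0
  kc:
    elastic_modulus_mpa: 2.4
    central_thickness_um: 450.0
    peripheral_thickness_um: 750.0
  corneal_diameter_mm: 11.5
  anterior_radius_mm: 7.8
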