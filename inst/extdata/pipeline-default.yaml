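# Fully populated default pipeline configuration.
# Units: diffusivities in 1e-3 mm^2/s, b-values in s/mm^2, ages in years,
# signal quantities in arbitrary scanner units.
cohort:
  group_sizes:
    young_control: 7
    age_control: 13
    mild_patient: 18
    severe_patient: 15
  age_mean:
    young_control: 27.4
    age_control: 51.9
    mild_patient: 55.6
    severe_patient: 58.1
  age_sd:
    young_control: 1.7
    age_control: 9.4
    mild_patient: 6.1
    severe_patient: 6.8
  n_female:
    young_control: 3
    age_control: 9
    mild_patient: 7
    severe_patient: 7
  baseline:
    wm_d: 1.5
    gm_d: 1.0
    wm_f1: 0.65
    gm_f1: 0.35
    S0: 100
  gap_multiplier: [1, 1, 0.75, 0.55]
  f1_multiplier: [1, 1, 0.95, 0.90]
  dispersion_multiplier: [1, 1, 1.2, 1.4]
  crossing_multiplier: [1, 1, 1, 1]
  crossing_prevalence: 0.10
  voxel_jitter:
    d: 0.08
    f1: 0.05
  subject_sd: 0.05
  tissue_sd: 0.02
  sigma: 12
  n_radiculopathy: 13
  grid_shape: [48, 48, 12]
  voxel_size: [0.65, 0.65, 3.0]
  shell_counts: [21, 42]
  shell_bvalues: [550, 1000]
  n_b0: 7
  seed: 1
map_source: truth
fit_restarts: 5
mi_bins: 64
intervals:
  FA_WM: [0.47, 0.67]
  f1_WM: [0.30, 0.55]
  MD_WM: [0.84, 1.26]
  MD_GM: [0.84, 1.26]
  d_WM: [1.70, 2.20]
  d_GM: [1.00, 1.48]
entry_p: 0.05
removal_p: 0.10
kmeans_restarts: 100
seed: 1
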