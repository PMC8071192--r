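# Default experiment configuration: the calibrated 15 HCC + 9 CCA cohort.
# Group means/SDs, structural-model coefficients and R^2 targets are the
# package defaults (see ?cohort_config); this file carries the scalar knobs.
cohort:
  n_hcc: 15
  n_cca: 9
  compression_levels: [0.0, 2.0, 4.0]   # kPa: basal + two balloon inflations
  phase_noise_sd: 0.03                  # rad per MRE phase sample
  pressure_noise_sd: 0.5                # mmHg per catheter read
  session_sdlog: 0.08                   # day-to-day modulus jitter (log-SD)
mre:
  support_radius: 8                     # tumor disk radius, voxels
  roi_margin: 3                         # in-plane ROI erosion, voxels
  n_repeatability: 5                    # HCC mice scanned twice
  grad_target: 2.4                      # max phase gradient per voxel, rad
histology:
  collagen_tile_px: 512
  collagen_pixel_size: 2.0              # um
  nucleus_pixel_size: 0.5               # um
  nucleus_field_area: 1.0               # mm^2
  overlap_fraction: 0.1                 # nuclei placed in touching pairs
stats:
  solid_stress_cutoff: 15.6             # mmHg, vessel-collapse threshold
  collagen_cutoff: 1.7                  # %, substantial collagen content
  p_enter: 0.05
  p_remove: 0.10
power:
  expected_auc: 0.85
  null_auc: 0.5
  alpha: 0.05
  power: 0.8
  neg_pos_ratio: 1.7
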