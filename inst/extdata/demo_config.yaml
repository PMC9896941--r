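# Demo pipeline configuration (synthetic data; equivalent to demo_config()).
# Run: Rscript inst/cli/polpulse.R all --config inst/extdata/demo_config.yaml --out demo_out
seed: 1
scene:
  volume_shape: [12, 72, 72]      # z, y, x voxels
  n_clusters: 2
  n_frames: 40
noise:
  exposure_time_ms: 50.0          # t_exp (phase B / test images)
  reference_exposure_ms: 200.0    # t_ref (high-quality references)
  read_noise_sd: 2.0
denoiser:
  type: gaussian                  # identity | gaussian | median
  sigma: [0.5, 1.0, 1.0]
qc_thresholds:                    # mandatory, no silent defaults
  min_resolution_nm: 800.0        # accept needs measured resolution <= this
  min_ssim: 0.3
  max_local_error_fraction: 0.5
  local_ssim_floor: 0.0
segmentation:
  smoothing_sigma: 1.0
  threshold_method: otsu
  min_volume_vox: 8
  background_subtract: yes
  erode_mask: 2
tracking:
  linking_radius_nm: 1000.0
  max_gap: 0
fluctuation:
  anchor: elongation
  max_lag_s: 16.0
  n_bootstrap: 200
pairs:
  n_pairs: 120
  noise_sd: 0.25
pseudotime:
  anchor_feature: ser5p_mean
  n_bootstrap: 100
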