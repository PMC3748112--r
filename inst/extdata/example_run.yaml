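# Example end-to-end run configuration for run_pipeline() / `panelpet run`.
geometry:
  panel_length_mm: 280
  panel_separation_mm: 300
  crystal_pitch_mm: 2
phantom:
  type: nema_iq
  pixel_size: 1
  background_activity: 5.3
  hot_ratio: 4
acquisition:
  n_decays: 200000
  timing_fwhm_ps: 300
  energy_fwhm_fraction: 0.13
  seed: 1
recon:
  roi: {x_min: -80, x_max: 80, y_min: -80, y_max: 80}
  n_iterations: 10
  n_subsets: 16
output:
  dir: runs/example
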