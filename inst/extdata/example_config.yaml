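# Example experiment configuration for run_experiment() and the CLI.
# Two clients with appearance shift and unequal lesion burden, desk scale.
data:
- client_id: siteA
  n_cases: 8
  volume_shape: 24
  target_ratio: 0.01
  lesion_radius_range: [2, 3]
  intensity_offset: 0
  noise_sigma: 5
- client_id: siteB
  n_cases: 8
  volume_shape: 24
  target_ratio: 0.04
  lesion_radius_range: [2, 3]
  intensity_offset: 50
  noise_sigma: 5
network:
  depth: 2
  base_channels: 4
federation:
  mode: fedmsrw
  n_rounds: 5
  iters_per_round: 50
  lr: 0.05
  lr_schedule: poly
  batch_size: 4
  patch_size: [16, 16, 16]
  master_seed: 1
inference:
  threshold: 0.5
cv:
  n_folds: 2
  seed: 1
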