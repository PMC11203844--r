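# Example experiment configuration: a reduced sweep that runs in a few
# minutes on one CPU. Units are Angstrom; residue indices are 0-based.
synth:
  n_residues: 282
  n_frames: 600
  class_proportions: {active: 0.10, intermediate: 0.80, inactive: 0.10}
  marker_pair: [95, 225]
  informative_residues: [14, 16, 18, 20, 22, 24, 26, 28]
  shift: 2.0
  noise_sd: 0.3
labeling:
  active_min: 14.0
  inactive_max: 8.5
  marker_pair: [95, 225]
resamplers:
  - {method: none}
  - {method: smoteenn, k_neighbors: 5, enn_neighbors: 3}
model:
  conv_blocks: [[16, 7, 2], [32, 7, 2]]
  dense_units: [64]
  dropout: 0.2
  learning_rate: 0.001
  epochs: 20
  batch_size: 64
  early_stop_patience: 4
explainers: [lrp, saliency]
assessment:
  noise_sd: 0.5
  stability_repeats: 3
  subset_size: 30
seed: 1
val_fraction: 0.2
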