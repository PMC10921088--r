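# Example experiment configuration for the command-line front end.
# Sections map onto the package constructors; omitted fields use defaults.

phantom:
  n_samples: 100
  image_size: [32, 32]
  lesion_area_range: [0.05, 0.2]

network:
  depth: 3
  base_channels: 8
  skip_mode: watunet
  input_size: [32, 32]

train:
  epochs: 6
  batch_size: 4
  learning_rate: 0.001

split:
  train_frac: 0.8
  val_frac: 0.1
  test_frac: 0.1

clahe:
  clip_limit: 2
  tile_grid: [8, 8]

skip_modes: [watunet, plain]
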