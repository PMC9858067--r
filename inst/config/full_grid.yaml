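# Full experiment grid: three spectral representations x three
# pretreatments, 1D-CNN, 8 repeated trainings on a fixed per-class
# Kennard-Stone 2:1 split. Values not fixed by the application are marked
# "# choice:".
synthetic:
  seed: 2023            # choice: data-generation seed
modalities: [fused, nirr, nirt]
methods: [np, fd, snv]
models: [cnn]
n_repeats: 8
base_seed: 1            # choice: first training seed; repeats use base_seed..base_seed+7
cnn:
  conv_filters: 64
  conv_kernel: 3
  pool_size: 3
  dense_units: 64
  n_classes: 3
  dropout_rate: 0.5     # choice: rate/placement not fixed by the architecture table
  epochs: 20            # choice: converges well before 20 on the synthetic task
  batch_size: 32        # choice
  learning_rate: 0.001  # choice: Adam step size
  relu_output: false    # choice: true reproduces the printed head literally
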