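# Example declarative pipeline configuration for read_pipeline_config().
seed: 1
sim:
  n_patients: 20
  epochs_per_patient: 30
  n_channels: 19
  fs: 250
  epoch_seconds: 4
  seizure_fraction: 0.06
augmentation:
  - method: none
  - method: smote
    k: 5
  - method: adasyn
    K: 5
  - method: class_weight
  - method: gan
    gan:
      variant: wgan_gp
      noise_dim: 32
      batch_size: 16
      epochs: 400
classifier:
  kind: rf
  n_trees: 300
evaluation:
  k: 10
output:
  dir: results/reports
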