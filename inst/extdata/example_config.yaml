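# Example pipeline configuration: any subset of the default_config() blocks
# may appear; unknown keys are rejected. Values shown are the defaults.
seed: 1
gabor:
  n_scales: 4
  n_orientations: 6
  gamma: 1.0
  eta: 1.0
  truncation_sd: 3
timing:
  duration_sec: 2.0
  sample_rate: 16000
  hop: 500
band:
  f_min: 220
  f_max: 3000
stft:
  n_fft: 1024
griffin_lim:
  iters: 60
traversal: hilbert
cnn:
  learning_rate: 1.0e-4
  epochs: 20
  batch_size: 32
forest:
  n_trees: 100
fusion:
  k_folds: 5
  lambda: 1.0e-4
  threshold: 0.5
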