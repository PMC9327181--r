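name: trivec
seed: 1
data:
  synthetic: true
split:
  mode: weak
  n_weak: 10
training:
  learning_rate: 0.005
  epochs_max: 40
  K: 64
  lambda: 0.01
  batch_size: 512

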