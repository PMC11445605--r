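# Observer error-model configuration (synthetic example)
true_karyotype:
  n_pairs: 9
  length_range: [2, 6]
  ci_range: [0.25, 0.45]
  seed: 2024
n_observers: 15
sigma_calibration: 0.05
sigma_arm: 0.03
sigma_shortarm_bias: 0.15
bias_mode: additive
seed: 2024
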