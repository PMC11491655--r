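# Default end-to-end experiment: the simulated study conditions.
schema_version: 1
seed: 7
cohort:
  preset: ukb_like
plan:
  sizes: [150, 300, 600, 1200, 2400]
  n_val: 1200
  mc_iterations: 10
protocol:
  max_rounds: 200
  patience: 10
  fl_clients_per_round: 32
  batch_size: 64
  lr: 0.005
  weight_decay: 0.0001
strategies: [central, fl, tm]
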