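# Example run configuration: one two-target pairing (0 and 90 deg at 5 deg/s,
# +1 deg steps) with its two single-target reference conditions.
conditions:
  - {n_targets: 1, speed: 5, direction: 0, step_size: 1}
  - {n_targets: 1, speed: 5, direction: 90, step_size: 1}
  - n_targets: 2
    speed: 5
    direction: [0, 90]
    step_size: 1
n_per_condition: 100
seed: 42
latency_B: 1000
cp_B: 1000
params:
  pursuit_latency_ms: 190
  pre_gain: 0.4
  post_gain: 0.8
  position_noise_sd: 0.1
  selection_coupling: 0.7
  pre_weight_modes: [0.2, 0.8]
  post_weight_sd: 0.1
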