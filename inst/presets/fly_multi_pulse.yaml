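config:
  rate: 10000
  chunk_samples: 2048
  channels: 9
  class_names: [pulse]
  class_roles: [event]
  use_stft: false
  kernel_count: 32
  kernel_size: 32
  tcn_stacks: 4
  separable_stacks: [1, 2]
postprocess:
  event_threshold: 0.5
  event_min_distance_s: 0.010
  fill_gap_s: 0.020
  min_duration_s: 0.020
  event_tolerance_s: 0.010
training:
  event_sigma_ms: 1.6
  fractions: [0.8, 0.1, 0.1]
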