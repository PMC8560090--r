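config:
  rate: 10000
  chunk_samples: 4096
  channels: 1
  class_names: [pulse, sine]
  class_roles: [event, segment]
  use_stft: false
  kernel_count: 32
  kernel_size: 32
  tcn_stacks: 3
postprocess:
  event_threshold: 0.7
  event_min_distance_s: 0.010
  fill_gap_s: 0.020
  min_duration_s: 0.020
  event_tolerance_s: 0.010
  segment_tolerance_s: 0.040
training:
  event_sigma_ms: 1.6
  syllable_gap_ms: 6.25
  fractions: [0.8, 0.1, 0.1]
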