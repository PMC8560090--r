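config:
  rate: 300000
  chunk_samples: 8192
  channels: 1
  class_names: [usv]
  class_roles: [segment]
  use_stft: true
  stft_pairs: 33
  stft_duration: 64
  stft_stride: 16
  kernel_count: 32
  kernel_size: 16
  tcn_stacks: 2
postprocess:
  fill_gap_s: 0.010
  min_duration_s: 0.005
  event_tolerance_s: 0.010
training:
  fractions: [0.8, 0.1, 0.1]
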