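config:
  rate: 44100
  chunk_samples: 8192
  channels: 1
  class_names: [ek, trill, tsik, twitter]
  class_roles: [segment, segment, segment, segment]
  use_stft: true
  stft_pairs: 33
  stft_duration: 64
  stft_stride: 16
  kernel_count: 32
  kernel_size: 16
  tcn_stacks: 2
postprocess:
  fill_gap_s: 0.005
  min_duration_s: 0.030
  event_tolerance_s: 0.040
training:
  fractions: [0.6, 0.2, 0.2]
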