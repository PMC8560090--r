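config:
  rate: 32000
  chunk_samples: 2048
  channels: 1
  # the six syllable types of one male's main motif
  class_names: [sylA, sylB, sylC, sylD, sylE, sylF]
  class_roles: [syllable, syllable, syllable, syllable, syllable, syllable]
  use_stft: true
  stft_pairs: 33
  stft_duration: 64
  stft_stride: 16
  kernel_count: 64
  kernel_size: 32
  tcn_stacks: 4
postprocess:
  fill_gap_s: 0.005
  min_duration_s: 0.030
  event_tolerance_s: 0.010
training:
  syllable_gap_ms: 6.25
  fractions: [0.8, 0.1, 0.1]
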