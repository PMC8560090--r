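Package: vocseg
Title: Annotation of Animal Vocalizations by Dilated-Convolution Sequence Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-wise annotation of acoustic signals such as fly courtship
    song, rodent ultrasonic vocalizations and bird song. A temporal
    convolutional network with an optional trainable short-time Fourier
    frontend maps raw single- or multi-channel audio to per-sample song-type
    confidence scores. The package provides the full pipeline: a seeded
    synthetic-song generator (pulse trains, sine song, labeled syllable
    sequences, controllable noise), target encoding and network training,
    chunked inference with event peak-picking and segment smoothing,
    tolerance-matched event evaluation metrics, signal-to-noise estimators,
    and unsupervised repertoire classification by neighbor-graph embedding
    and density clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
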