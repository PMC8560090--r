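---
title: "Methods: how vocseg labels animal song"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how vocseg labels animal song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vocseg)
```

`vocseg` annotates acoustic signals — fly courtship song, rodent ultrasonic
vocalizations, bird syllables — by mapping raw audio sample-by-sample to a
probability over song types. This vignette describes the model, the training
and inference procedures, the evaluation metrics, and the design decisions
behind them, including the points where the method leaves genuine room for
interpretation.

## The model

The network transforms a waveform $x(t, \gamma)$ (time $t$, channel
$\gamma$) into per-sample confidence scores $y_i(t)$, one per song type plus
an implicit *no song* class, with $\sum_i y_i(t) = 1$.

### Trainable STFT frontend (optional)

For high-rate or spectrally complex signals (mouse, marmoset, birds) the
first layer is a strided pair of one-dimensional convolutions whose kernels
are *initialized* as the real and imaginary parts of DFT kernels:

$$x(i, f) = \sum_{\tau=0}^{T-1} x(i s + \tau)\left[\cos(2\pi f \tau / T) -
\mathrm{i}\,\sin(2\pi f \tau / T)\right], \qquad
y(i, f) = \log_{10} |x(i, f)|.$$

At initialization this is exactly a log-magnitude spectrogram with a
rectangular window of length $T$ and stride $s$ (the test suite asserts
agreement with an FFT oracle to $10^{-4}$); during training the kernels are
free to adapt. The stride downsamples the sequence by a factor $s$, which is
what makes very high sampling rates (300 kHz mouse audio) tractable.
Defaults: 33 filter pairs, $T = 64$, $s = 16$. Two numerical choices the
formula itself leaves open:

* a floor inside the logarithm, $\log_{10}(\max(|x|, 10^{-10}))$, keeps
  silent frames finite;
* the magnitude is $\sqrt{\Re^2 + \Im^2}$; the squared-magnitude (power)
  reading of the formula is available via the frontend's `magnitude`
  setting.

For pulsatile fly song the frontend is omitted (the loss of temporal
resolution hurts pulse timing), matching the species presets.

### Temporal convolutional stacks

The core is a stack of TCN blocks, each a stack of five residual blocks:

1. a dilated convolution
   $y_i(t) = \sum_{\tau,\gamma} k_i(\tau, \gamma)\, x(t - a\tau, \gamma)$
   with dilation $a$ doubling across the five blocks (1, 2, 4, 8, 16),
2. a rectifier $\max(0, y_i)$,
3. a normalization $y_i / (\max(|y_i|) + 10^{-5})$,
4. a residual addition $o(t) = x(t) + z(t)$ (with a 1×1 projection when
   widths differ, i.e. at the first block).

Every block's normalized output $z$ also feeds a skip path; the skip
outputs are linearly combined by a single dense layer plus softmax into the
per-frame class probabilities. "Linearly combined through one dense layer"
admits two readings — summing the skip outputs first, or concatenating them
— which span different model families (the sum constrains all blocks to
share one readout basis). The default is the sum, for parameter economy;
`skip_mode = "concat"` selects the concatenation. When the frontend downsampled the input, the
probabilities are restored to the audio rate by repeating each frame $s$
times.

**Normalization axis.** The normalization formula names no axis. Taking the
maximum over the *time* axis of the current chunk would make every output
depend on the whole chunk, so identical audio would yield different
confidences depending on how the recording was chunked — contradicting the
guarantee that overlapped chunked inference reproduces the whole-recording
result. We therefore take the maximum over the *kernel* axis at each time
step. Every layer is then local in time, and chunked inference with trimmed
margins is exact (asserted to $10^{-5}$ for every preset); the intent of the
layer — activations with maximum absolute value near 1 — is preserved.

**Padding.** Convolutions are zero-padded, centered ("same"); the tool is
offline-first and a non-causal context window is strictly more informative.
Chunk margins contaminated by the padding are discarded during inference
(half the total convolutional span per side, plus the frames whose STFT
window crosses the chunk end); the recording's own first and last margins
are retained from the edge chunks, where the zero padding coincides with the
whole-recording computation.

**Separable convolutions.** For multi-channel audio, early stacks can use
time-channel separable convolutions: one shared temporal kernel per block
applied to every channel, followed by $N$ channel-mixing kernels —
$\tau + N\gamma$ parameters instead of $\tau\gamma N$. The parameter
accounting is exposed by `parameter_count()` and asserted in the tests.

**Initialization.** Fan-based uniform (Glorot) initialization under a user
seed everywhere except the frontend's DFT kernels.

### Structural presets

`load_preset()` ships the configurations used across species families
(fly single/multi-channel, mouse, marmoset, Bengalese and zebra finch),
including rate, chunk length, channel count, frontend usage, kernel counts
and sizes, stack counts, separable-stack indices, and the post-processing
defaults below. The bird presets carry placeholder six-type vocabularies;
real repertoires replace them per individual.

## Training

Targets are encoded per sample (`encode_targets()`):

* segment classes are binary on $[{\rm start}, {\rm stop})$;
* event classes are unit-peak Gaussian bumps, $\sigma = 1.6$ ms, truncated
  at $\pm 4\sigma$ — encoding uncertainty in the annotated pulse time;
* for bird-style `syllable` classes, a 6.25 ms *no song* gap (200 samples at
  32 kHz) is relabeled between adjacent syllables so on- and offsets are
  unambiguous label changes;
* *no song* completes each row to 1. Where song values overlap (a bump tail
  reaching into a neighboring segment) the song entries are renormalized
  proportionally first; overlapping *segments* of different types are
  rejected. Row sums are exactly 1, asserted over 1000 random annotation
  tables.

Training minimizes the categorical cross-entropy with Adam (batch size 32,
up to 400 epochs, early stopping with patience 20 on the validation loss,
best-validation weights restored). Chunks are drawn from the training
intervals with a fresh random offset each epoch so chunk boundaries do not
align with annotation boundaries. When the frontend downsamples, the loss is
computed at the frame rate against stride-group means of the sample-rate
targets (equivalent to the repeat-upsampled loss up to a constant). The
learning rate is not part of the published protocol; the package default is
$10^{-3}$, a standard Adam setting that converges quickly on the synthetic
tasks, and it is exposed in `train_config()`. Class weighting is off by
default; inverse-frequency weights are available behind a flag.

Splits (`split_dataset()`) take contiguous validation and test blocks from
the first, middle or last part of each recording (drawn per recording under
a seed; a shared draw is available), defaults 80:10:10 with 60:20:20
selectable for unevenly distributed repertoires.

## Inference and annotation generation

`predict_confidence()` runs overlapped chunks and trims contaminated
margins, as above. Event classes are decoded by `detect_events()`: local
maxima of the class confidence above a threshold (default 0.7; 0.5 for
multi-channel fly data), greedily suppressed so surviving peaks are at least
`min_distance` (default 10 ms) apart, higher peaks first. Peaks on plateaus
— which arise after repeat upsampling — resolve to the plateau's first
sample; optional quadratic interpolation refines peak times below the
stride.

Segment classes are decoded by per-sample argmax (`label_segments()`, ties
to the lowest class index; *no song* is ordered last so ties never silently
favor it), then smoothed (`smooth_segments()`): *no song* gaps shorter than
`fill_gap` between runs of the same label are filled (flies 20 ms, mice
10 ms, marmosets/birds 5 ms), then runs shorter than `min_duration` are
removed (flies 20 ms, mice 5 ms, marmosets/birds 30 ms). Filling precedes
removal; because removal can create a new fillable gap, the two steps are
iterated to a fixpoint — in practice one extra pass at most — which makes
the operation idempotent and its postcondition unambiguous. Gaps containing
a *different* song label are not filled. Finally `majority_vote()` labels
each detected segment with the mode of its sample labels (ties to the
earliest label in the segment).

## Evaluation

`match_events()` pairs predictions with true events within a tolerance
(10 ms default; 40 ms for boundaries that fade in and out, like fly sine
song and marmoset calls). When several predictions share a nearest true
event only the nearest becomes a true positive; the rest are re-matched to
remaining true events within tolerance or counted as false positives. This
is implemented as greedy matching in ascending pair distance, which the
tests verify attains the brute-force bipartite optimum whenever events are
separated by more than twice the tolerance. Unmatched true events are false
negatives. Pseudo true negatives for event classes — only used to complete
confusion matrices — are $\lfloor {\rm duration} / (2\,{\rm tol}) \rfloor -
n_{\rm true}$, clipped at zero.

From the counts: precision $P = TP/(TP+FP)$, recall $R = TP/(TP+FN)$,
$F_1 = 2PR/(P+R)$ (the harmonic-mean formula), accuracy
$(TP+TN)/(TP+TN+FP+FN)$, temporal precision as the median absolute distance
of matched pairs, and the sequence error rate as the Levenshtein distance
between true and predicted syllable label sequences divided by the true
length. Sample-wise and per-syllable (label-mode) confusion matrices cover
segment classes.

### SNR estimators

Three estimators, matching the signal families (all gain-invariant, RMS
defined as $\sqrt{\textrm{mean}(x^2)}$):

* **pulse** — 20 ms windows centered on the pulse energy peak; SNR = center
  RMS (7.5–12.5 ms) / margin RMS (first and last 5 ms); multi-channel: the
  channel with the highest center RMS;
* **sine** — segment RMS over the RMS of 200 ms flanks with a 10 ms buffer
  (a segment ending at 1000 ms uses 1010–1210 ms), excluding flank samples
  annotated as song;
* **mouse** — additive power model on 1 ms windows:
  ${\rm SNR}(t) = \max(\sigma^2_{\rm total}(t) - \sigma^2_{\rm noise}, 0) /
  \sigma^2_{\rm noise}$. The constant noise power is not given an estimator
  in the protocol; we use a robust low percentile (default the 10th) of the
  windowed power, which slightly underestimates the noise floor and
  therefore biases SNR upward by a few percent; the percentile is exposed.

## Unsupervised repertoire classification

Event waveforms are cut (15 ms), aligned to their energy peak, unit-norm
scaled and sign-adjusted. Syllables become mel-spectrogram patches (64
bands, window 1024, hop 128 — unspecified in the protocol, exposed in the
API): each band is divided by its median over time (the frequency-specific
noise floor), log-transformed, thresholded (0 for mouse-like, 2 for
marmoset/bird-like signals) by subtract-and-clip so features stay
non-negative, log-resized in time to $\max(1, \mathrm{round}(\ln W \cdot
8))$ columns, zero-padded to the longest item, and optionally aligned to the
peak frequency keeping 40 bands (clamped and zero-padded at band edges).

The 2-D embedding is a spectral embedding of the k-nearest-neighbor graph:
locally scaled Gaussian affinities, normalized graph Laplacian, the two
leading non-trivial eigenvectors weighted diffusion-map style by
$(1-\lambda/2)^t$ (default $t = 8$) so that between-group modes dominate.
This is the same neighbor-graph construction UMAP builds on, chosen here
for determinism and freedom from iterative-layout dependencies; `min_dist`
is accepted for interface compatibility and ignored. Clustering is either a
density-based method (DBSCAN-style; `min_samples = 10`,
`min_cluster_size = 20`, noise label −1, `eps` defaulting to 5% of the
embedding diameter) in the spirit of HDBSCAN, or k-means with 40 groups for
repertoires without visible density clusters. Agreement with manual labels
is scored by homogeneity, completeness and their harmonic mean (v-measure),
computed from conditional entropies.

## The synthetic-song generator

The generator provides ground-truth-perfect data with the statistical
structure of the real signals: Gabor pulses (Gaussian-windowed cosines,
matching the biphasic multi-cycle pulse shape; the envelope peak is the
ground-truth event time) in trains with 35–45 ms jittered inter-pulse
intervals and carriers of 180–500 Hz; 150 Hz sine song with raised-cosine
ramps; bird-like syllables from frequency-contour templates with harmonics;
Gaussian background noise of controlled RMS; pulsatile noise as
single-cycle clicks at Poisson times (the false-positive pathway fly
recordings suffer from); and per-channel gain projection for multi-channel
setups. Everything is bit-reproducible from a seed.

What it does *not* emulate: room acoustics and reverberation, microphone
directivity, animal movement (time-varying gains), overlapping singers,
non-stationary noise, and species-accurate spectro-temporal detail. Passing
the recovery tests therefore demonstrates that the estimation machinery
works — targets, optimization, decoding, metrics — not that any particular
field recording will be annotated at a given accuracy.

## Problem sizes in the test suite

The packaged tests run on one CPU within minutes by scaling the experiments
to: a 320 s two-recording fly-like corpus (high SNR) for the
parameter-recovery experiment, trained for up to 30 epochs on a reduced
network (1 TCN stack, 16 kernels of 16 samples, STFT frontend) with
learning rate $3\times10^{-3}$ and chunk length 8192 — reaching held-out
event F1 and sample-wise sine F1 of at least 0.9 at 10 ms tolerance, with a
noise sweep confirming recall does not increase as SNR decreases; 10 s of
synthetic audio per species preset for the chunked-inference equivalence;
1000 random instances for the matching oracle; all 3-letter strings to
length 3 (plain recursive oracle) plus a 300-string sample to length 6
(independent C implementation) for the edit distance; and 450 syllables of
three template types for the clustering recovery (v-measure at least 0.9).

## Known limitations

* Pure-R training: practical for the reduced synthetic experiments and for
  small corpora; training the full presets on hours of audio calls for a
  GPU implementation of the same architecture.
* The normalization-axis and magnitude-vs-power readings are interpretation
  points (documented above and switchable where meaningful).
* No multi-animal overlap resolution; mutually exclusive labels per sample.
* The density clusterer requires an `eps` scale (automatic default);
  hierarchical eps-free selection as in HDBSCAN is not implemented.
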