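test_that("waveform preprocessing aligns, normalizes and fixes sign", {
  rate <- 10000
  pt <- make_pulse_train(pulse_train_params(train_length = 8, amplitude = 0.7),
                         rate, seed = 2)
  comp <- list(list(waveform = pt$waveform, at = 0.2,
                    annotations = events_to_annotations(pt$event_times, "pulse")))
  rec <- make_recording(comp, 2, rate, seed = 1)$recording
  ev <- pt$event_times + 0.2
  W <- preprocess_waveforms(rec, ev, window_ms = 15)
  expect_equal(nrow(W), 8)
  expect_equal(apply(W, 1, function(r) sqrt(sum(r^2))), rep(1, 8))
  expect_true(all(apply(W, 1, function(r) r[which.max(abs(r))]) > 0))

  # a waveform and its negation give identical rows
  rec_neg <- rec; rec_neg$samples <- -rec$samples
  W2 <- preprocess_waveforms(rec_neg, ev, window_ms = 15)
  expect_equal(W2, W)

  # two shape families: within-family distances < between-family distances
  st <- make_sine_song(sine_song_params(carrier_hz = 450, duration_ms = 8,
                                        ramp_ms = 3, amplitude = 0.7), rate)
  comp2 <- c(comp, lapply(seq(0.9, 1.4, by = 0.1), function(at) {
    list(waveform = st$waveform, at = at, annotations = annotations())
  }))
  rec3 <- make_recording(comp2, 2, rate, seed = 1)$recording
  ev3 <- c(ev, seq(0.9, 1.4, by = 0.1) + 0.004)
  W3 <- preprocess_waveforms(rec3, ev3, window_ms = 15)
  fam <- c(rep(1, 8), rep(2, 6))
  D <- as.matrix(dist(W3))
  within <- D[outer(fam, fam, "==") & upper.tri(D)]
  between <- D[outer(fam, fam, "!=")]
  expect_lt(max(within), min(between))

  expect_warning(preprocess_waveforms(rec, 0.001), "skipped")
})

test_that("spectrogram preprocessing is noise-floor normalized and gain invariant", {
  rate <- 32000
  set.seed(3)
  noise <- recording(rnorm(rate, sd = 0.1), rate)
  seg <- data.frame(onset = c(0.2, 0.6), offset = c(0.3, 0.7))
  # stationary noise with bird-style threshold 2: features are all zero
  S2 <- preprocess_spectrograms(noise, seg, threshold = 2)
  expect_true(all(S2 == 0))
  # with threshold 0 the residual fluctuations around the floor stay small
  S0 <- preprocess_spectrograms(noise, seg, threshold = 0)
  expect_true(all(S0 >= 0))
  expect_lt(mean(S0), 0.2)

  # identical syllables at different amplitudes: near-identical features
  syl <- make_syllable_sequence(three_templates()[1], 2, gap_ms = c(400, 400),
                                rate = rate, seed = 4)
  x <- syl$waveform + rnorm(length(syl$waveform), sd = 1e-4)
  segs <- data.frame(onset = syl$annotations$start_seconds,
                     offset = syl$annotations$stop_seconds)
  A <- preprocess_spectrograms(recording(x, rate), segs, threshold = 2)
  B <- preprocess_spectrograms(recording(5 * x, rate), segs, threshold = 2)
  expect_lt(max(abs(A - B)) / max(A), 0.02)

  expect_error(preprocess_spectrograms(noise, data.frame(onset = 0.5005,
                                                         offset = 0.5008)),
               "shorter than one spectrogram frame")
})

test_that("peak alignment centers the retained bands on the tone", {
  rate <- 32000
  x <- 0.5 * sin(2 * pi * 8000 * (0:63999) / rate) +
    stats::rnorm(64000, sd = 0.01)
  seg <- data.frame(onset = c(0.4, 1.2), offset = c(0.6, 1.4))
  S <- preprocess_spectrograms(recording(x, rate), seg, threshold = 0,
                               retained_bands = 40)
  expect_equal(dim(S)[2], 40)
  for (i in 1:2) {
    prof <- rowMeans(S[i, , ])
    expect_lte(abs(which.max(prof) - 21), 1)  # centered on the peak band
  }
})

test_that("the neighbor-graph embedding separates structure and keeps duplicates together", {
  set.seed(11)
  blobA <- matrix(rnorm(40 * 6, mean = 0), ncol = 6)
  blobB <- matrix(rnorm(40 * 6, mean = 8), ncol = 6)
  X <- rbind(blobA, blobB)
  emb <- embed_2d(X, n_neighbors = 10, seed = 1)
  expect_equal(dim(emb), c(80, 2))
  lab <- rep(1:2, each = 40)
  D <- as.matrix(dist(emb))
  within <- max(D[outer(lab, lab, "==")])
  between <- min(D[outer(lab, lab, "!=")])
  expect_gt(between, within)

  # duplicated rows land on top of each other
  Xd <- rbind(X, X[3, ], X[50, ])
  ed <- embed_2d(Xd, n_neighbors = 10, seed = 1)
  expect_lt(sqrt(sum((ed[81, ] - ed[3, ])^2)), 1e-8)
  expect_lt(sqrt(sum((ed[82, ] - ed[50, ])^2)), 1e-8)

  expect_error(embed_2d(X[1:5, ], n_neighbors = 10), "n_neighbors")
})

test_that("density clustering recovers separated blobs; kmeans honors k", {
  set.seed(13)
  blobs <- rbind(matrix(rnorm(200, sd = 0.3), ncol = 2),
                 matrix(rnorm(200, sd = 0.3) + 6, ncol = 2),
                 cbind(rnorm(100, 12, 0.3), rnorm(100, 0, 0.3)))
  cl <- cluster_embedding(blobs, "density")
  expect_equal(length(setdiff(unique(cl$labels), -1L)), 3)
  truth <- rep(1:3, each = 100)
  expect_gt(cluster_agreement(truth, cl$labels)$v, 0.95)

  k1 <- cluster_embedding(blobs, "kmeans", k = 1, seed = 2)
  expect_equal(unique(k1$labels), 1L)
  kn <- cluster_embedding(blobs[1:25, ], "kmeans", k = 25, seed = 2)
  expect_equal(sort(kn$labels), 1:25)

  expect_warning(cluster_embedding(blobs[1:5, ], "density",
                                   min_cluster_size = 20), "noise")
})

test_that("agreement scores follow their conditional-entropy definitions", {
  a <- rep(c("x", "y"), each = 50)
  same <- cluster_agreement(a, rep(1:2, each = 50))
  expect_equal(unlist(same), c(homogeneity = 1, completeness = 1, v = 1))

  onecl <- cluster_agreement(a, rep(1, 100))
  expect_equal(onecl$completeness, 1)
  expect_equal(onecl$homogeneity, 0)

  # each manual class split into two pure clusters: homogeneity 1,
  # completeness = 1 - log(2)/log(4) = 0.5
  split4 <- cluster_agreement(a, rep(1:4, each = 25))
  expect_equal(split4$homogeneity, 1)
  expect_equal(split4$completeness, 0.5)
  expect_equal(split4$v, 2 / 3)

  # v is symmetric when the two labelings swap roles
  set.seed(17)
  m <- sample(letters[1:3], 60, replace = TRUE)
  c2 <- sample(1:4, 60, replace = TRUE)
  expect_equal(cluster_agreement(m, c2)$v, cluster_agreement(as.character(c2), m)$v)
})
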