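#' Extract aligned, normalized event waveforms
#'
#' For each event, a window of `window_ms` is cut from the recording,
#' re-centered on the peak of the squared amplitude, divided by its
#' Euclidean norm, and sign-flipped so that the dominant lobe (the sample of
#' maximal absolute amplitude) is positive. For multi-channel recordings the
#' channel with the largest peak energy within the window is used. Events
#' closer than half a window to the recording edge are skipped with a
#' warning; all-zero windows are skipped likewise.
#'
#' @param rec a [recording()].
#' @param event_times event times in seconds.
#' @param window_ms waveform duration in ms (default 15).
#' @return matrix `[n x samples]` of unit-norm waveforms, with attribute
#'   `times` giving the retained event times.
#' @export
preprocess_waveforms <- function(rec, event_times, window_ms = 15) {
  rate <- rec$rate
  half <- seconds_to_sample(window_ms / 2000, rate)
  n <- nrow(rec$samples)
  rows <- list(); times <- numeric()
  empty <- matrix(numeric(), 0, 2L * half)
  for (tt in event_times) {
    c0 <- seconds_to_sample(tt, rate)
    if (c0 - 2L * half < 0 || c0 + 2L * half >= n) {
      warning(sprintf("event at %.4f s too close to the edge; skipped", tt))
      next
    }
    win <- rec$samples[(c0 - half + 1L):(c0 + half), , drop = FALSE]
    ch <- which.max(apply(win^2, 2, max))
    # re-center on the peak energy, then cut the final window
    pk <- which.max(win[, ch]^2) + (c0 - half) - 1L
    w <- rec$samples[(pk - half + 1L):(pk + half), ch]
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) {
      warning(sprintf("all-zero window at %.4f s; skipped", tt))
      next
    }
    w <- w / nrm
    if (w[which.max(abs(w))] < 0) w <- -w
    rows[[length(rows) + 1L]] <- w
    times <- c(times, tt)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "times") <- times
  out
}

# mel filterbank [n_mels x n_bins] over FFT bins of a window of n_fft samples
mel_filterbank <- function(n_mels, n_fft, rate, f_min = 0, f_max = rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_bins <- n_fft %/% 2 + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * rate / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; cn <- pts[m + 1L]; hi <- pts[m + 2L]
    up <- (bin_hz - lo) / max(cn - lo, 1e-12)
    down <- (hi - bin_hz) / max(hi - cn, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# mel power spectrogram [n_mels x frames] with hann window; frame i covers
# samples (i-1)*hop + 1 .. (i-1)*hop + window
mel_spectrogram <- function(x, rate, n_mels = 64, window = 1024, hop = 128) {
  if (length(x) < window) stop("signal shorter than one spectrogram frame")
  starts <- seq.int(1L, length(x) - window + 1L, by = hop)
  idx <- outer(0:(window - 1L), starts, `+`)
  Fm <- matrix(x[idx], nrow = window) *
    (0.5 - 0.5 * cos(2 * pi * (0:(window - 1L)) / window))
  spec <- Mod(stats::mvfft(Fm))^2
  spec <- spec[seq_len(window %/% 2 + 1L), , drop = FALSE]
  mel <- mel_filterbank(n_mels, window, rate) %*% spec
  attr(mel, "frame_times") <- (starts - 1L + window / 2) / rate
  mel
}

#' Preprocess syllable spectrograms for clustering
#'
#' Implements the spectrogram pipeline for repertoire clustering: a mel
#' power spectrogram of the whole recording is computed; each spectral band
#' is divided by its frequency-specific noise floor (the median of that band
#' over time), log-transformed, then thresholded (values below `threshold`
#' set to zero; threshold 0 for mouse-like, 2 for marmoset/bird-like
#' signals). Each syllable's frames are cut out and the time axis is
#' log-resized to `max(1, round(log(W) * scaling_factor))` columns
#' (compressing duration differences), then zero-padded to the longest
#' syllable. Optionally the frequency axis is aligned to each syllable's
#' peak frequency (argmax of the time-averaged spectrogram), retaining
#' `retained_bands` bands around the peak (clamped and zero-padded at the
#' edges), which makes clustering robust to jitter in thin spectral
#' contours.
#'
#' @param rec a [recording()] (channel 1 is used).
#' @param segments data frame with `onset`/`offset` in seconds.
#' @param n_mels,window,hop mel-spectrogram parameters.
#' @param threshold log-magnitude threshold (subtract-and-clip at zero).
#' @param scaling_factor time log-resize factor (default 8).
#' @param retained_bands if non-`NULL`, align to the peak frequency and keep
#'   this many bands (e.g. 40).
#' @return array `[n x bands x time]` of non-negative features.
#' @export
preprocess_spectrograms <- function(rec, segments, n_mels = 64, window = 1024,
                                    hop = 128, threshold = 0,
                                    scaling_factor = 8, retained_bands = NULL) {
  stopifnot(inherits(rec, "vocseg_recording"), nrow(segments) >= 1)
  mel <- mel_spectrogram(rec$samples[, 1], rec$rate, n_mels, window, hop)
  ft <- attr(mel, "frame_times")
  floor_band <- apply(mel, 1, stats::median)
  norm <- mel / pmax(floor_band, 1e-300)
  lg <- log10(pmax(norm, 1e-12))
  lg <- pmax(lg - threshold, 0)

  items <- list()
  for (i in seq_len(nrow(segments))) {
    sel <- which(ft >= segments$onset[i] & ft < segments$offset[i])
    if (!length(sel)) {
      stop(sprintf("segment %d shorter than one spectrogram frame", i))
    }
    S <- lg[, sel, drop = FALSE]
    W <- ncol(S)
    new_w <- max(1L, as.integer(round(log(W) * scaling_factor)))
    out <- matrix(0, n_mels, new_w)
    if (W == 1L) {
      out[, 1] <- S[, 1]
    } else {
      grid <- seq(1, W, length.out = new_w)
      for (b in seq_len(n_mels)) {
        out[b, ] <- stats::approx(seq_len(W), S[b, ], xout = grid)$y
      }
    }
    items[[i]] <- out
  }
  max_w <- max(vapply(items, ncol, 0L))
  n_bands <- if (is.null(retained_bands)) n_mels else as.integer(retained_bands)
  stack <- array(0, dim = c(length(items), n_bands, max_w))
  for (i in seq_along(items)) {
    S <- items[[i]]
    if (!is.null(retained_bands)) {
      peak <- which.max(rowMeans(S))
      half <- retained_bands %/% 2L
      src <- (peak - half):(peak - half + retained_bands - 1L)
      keep <- src >= 1L & src <= n_mels
      A <- matrix(0, retained_bands, ncol(S))
      A[which(keep), ] <- S[src[keep], , drop = FALSE]
      S <- A
    }
    stack[i, , seq_len(ncol(S))] <- S
  }
  stack
}

#' Two-dimensional neighbor-graph embedding
#'
#' Reduces a feature set to two dimensions with a spectral embedding of the
#' k-nearest-neighbor graph: locally scaled Gaussian affinities on the kNN
#' graph, then the two leading non-trivial eigenvectors of the normalized
#' graph Laplacian, weighted diffusion-map style by `(1 - lambda)^t` so that
#' slow (between-group) modes dominate fast (within-group) modes. This is
#' the same neighbor-graph manifold construction UMAP-style methods build
#' on, and it is fully deterministic (eigenvector signs are canonicalized),
#' so duplicated inputs always land on identical coordinates. `min_dist` and
#' `seed` are accepted for interface compatibility with UMAP-style callers;
#' neither affects the spectral layout.
#'
#' @param features numeric matrix `[n x d]` or an array (flattened over all
#'   but the first dimension).
#' @param n_neighbors neighborhood size (default 15).
#' @param min_dist unused; see above.
#' @param seed unused; see above.
#' @param diffusion_time exponent `t` of the eigenvalue weighting.
#' @return numeric matrix `[n x 2]`.
#' @export
embed_2d <- function(features, n_neighbors = 15, min_dist = 0.5, seed = 1L,
                     diffusion_time = 8) {
  if (is.array(features) && length(dim(features)) > 2) {
    features <- matrix(features, nrow = dim(features)[1])
  }
  n <- nrow(features)
  if (n <= n_neighbors) stop("need more samples than n_neighbors")
  D <- as.matrix(stats::dist(features))
  # locally scaled Gaussian affinities on the kNN graph
  knn_d <- apply(D, 1, function(r) sort(r)[n_neighbors + 1L])
  sigma <- pmax(knn_d, 1e-12)
  W <- exp(-D^2 / outer(sigma, sigma))
  keep <- D <= matrix(knn_d, n, n) | D <= matrix(knn_d, n, n, byrow = TRUE)
  W[!keep] <- 0
  diag(W) <- 0
  d <- pmax(rowSums(W), 1e-12)
  Lsym <- diag(n) - W / sqrt(outer(d, d))
  eg <- eigen(Lsym, symmetric = TRUE)
  lam <- pmin(pmax(eg$values[c(n - 1L, n - 2L)], 0), 2)
  coords <- eg$vectors[, c(n - 1L, n - 2L), drop = FALSE] / sqrt(d)
  coords <- coords * rep((1 - lam / 2)^diffusion_time, each = n)
  # canonical sign: largest-magnitude coordinate positive
  for (j in 1:2) {
    k <- which.max(abs(coords[, j]))
    if (coords[k, j] < 0) coords[, j] <- -coords[, j]
  }
  coords <- scale(coords, center = TRUE, scale = FALSE)
  dimnames(coords) <- NULL
  coords[, 1:2, drop = FALSE]
}

#' Cluster an embedding
#'
#' `method = "density"`: a density-based clusterer (DBSCAN-style) with
#' `min_samples` neighbors within `eps` defining core points; clusters
#' smaller than `min_cluster_size` are dissolved into noise; noise points
#' get label `-1`. `eps = NULL` picks 5% of the embedding diameter, which
#' separates compact groups in a well-spread embedding. `method = "kmeans"`:
#' k-means with `k` groups (default 40, as used for repertoires without
#' visible density clusters), seeded.
#'
#' @param embedding numeric matrix `[n x 2]` (any dimensionality works).
#' @param method `"density"` or `"kmeans"`.
#' @param min_samples core-point neighborhood count (default 10).
#' @param min_cluster_size minimal cluster size (default 20).
#' @param eps density neighborhood radius; `NULL` for the automatic choice.
#' @param k number of k-means clusters (default 40).
#' @param seed integer seed (k-means starts).
#' @return list of class `vocseg_clusters` with `labels` (integers, `-1` =
#'   noise), `embedding` and `method`.
#' @export
cluster_embedding <- function(embedding, method = c("density", "kmeans"),
                              min_samples = 10, min_cluster_size = 20,
                              eps = NULL, k = 40, seed = 1L) {
  method <- match.arg(method)
  n <- nrow(embedding)
  if (method == "kmeans") {
    set.seed(seed)
    k <- min(k, n)
    labels <- if (k == n) seq_len(n) else
      stats::kmeans(embedding, centers = k, nstart = 10, iter.max = 100)$cluster
  } else {
    if (n < min_cluster_size) {
      warning("fewer points than min_cluster_size; all points labeled noise")
      labels <- rep(-1L, n)
    } else {
      D <- as.matrix(stats::dist(embedding))
      if (is.null(eps)) eps <- 0.05 * max(D, 1e-12)
      labels <- dbscan_labels(D, eps, min_samples)
      for (cl in setdiff(unique(labels), -1L)) {
        if (sum(labels == cl) < min_cluster_size) labels[labels == cl] <- -1L
      }
      labels <- relabel_consecutive(labels)
    }
  }
  structure(list(labels = as.integer(labels), embedding = embedding,
                 method = method), class = "vocseg_clusters")
}

dbscan_labels <- function(D, eps, min_samples) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}

relabel_consecutive <- function(labels) {
  pos <- sort(setdiff(unique(labels), -1L))
  out <- labels
  for (i in seq_along(pos)) out[labels == pos[i]] <- i
  out
}

#' Agreement between a clustering and manual labels
#'
#' Conditional-entropy scores: homogeneity `1 - H(manual|cluster)/H(manual)`
#' (each cluster contains one manual class), completeness
#' `1 - H(cluster|manual)/H(cluster)` (each manual class lands in one
#' cluster), and the v-measure, their harmonic mean. Degenerate single-class
#' cases score 1 by convention.
#'
#' @param manual,clusters equal-length label vectors.
#' @return list with `homogeneity`, `completeness`, `v`.
#' @export
cluster_agreement <- function(manual, clusters) {
  stopifnot(length(manual) == length(clusters))
  N <- length(manual)
  tab <- table(manual, clusters)
  p <- tab / N
  pm <- rowSums(p); pc <- colSums(p)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  Hm <- H(pm); Hc <- H(pc)
  Hmc <- -sum(p[p > 0] * log((p / rep(pc, each = nrow(p)))[p > 0]))
  Hcm <- -sum(p[p > 0] * log((p / pm[row(p)])[p > 0]))
  h <- if (Hm == 0) 1 else 1 - Hmc / Hm
  c_ <- if (Hc == 0) 1 else 1 - Hcm / Hc
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  list(homogeneity = h, completeness = c_, v = v)
}
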