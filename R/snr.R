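#' Signal-to-noise ratio estimators
#'
#' Three estimators tailored to the signal families the annotator is used
#' on. All return dimensionless amplitude ratios and are invariant to a
#' global gain applied to the recording.
#'
#' `snr_pulse()`: per event, a 20 ms waveform centered on the peak of the
#' pulse energy is cut; SNR is the RMS of the window center (7.5-12.5 ms)
#' over the RMS of the margins (first and last 5 ms). For multi-channel
#' recordings the channel with the highest center RMS is used.
#'
#' `snr_sine()`: per sine segment, SNR is the RMS inside the segment over
#' the RMS of the 200 ms before and after it (10 ms buffer; e.g. a segment
#' ending at 1000 ms uses 1010-1210 ms as noise). Samples annotated with any
#' of `exclude_labels` (default sine and pulse) are excluded from the noise
#' flanks. Multi-channel: the channel with the largest signal RMS.
#'
#' `snr_mouse()`: per-sample SNR under an additive noise model. The total
#' power per 1 ms window is computed; the noise floor is a robust
#' low-percentile estimate of that windowed power over time; then
#' `SNR(t) = max(power(t) - floor, 0) / floor`.
#'
#' @param rec a [recording()].
#' @param event_times event times in seconds.
#' @param window_s pulse window length (default 0.020).
#' @param margin_s pulse margin duration at each end (default 0.005).
#' @param center_s pulse center window as `c(from, to)` within the window
#'   (default `c(0.0075, 0.0125)`).
#' @return data frame of class `vocseg_snr` with per-event / per-segment /
#'   per-sample SNR values and a method tag.
#' @export
snr_pulse <- function(rec, event_times, window_s = 0.020, margin_s = 0.005,
                      center_s = c(0.0075, 0.0125)) {
  stopifnot(inherits(rec, "vocseg_recording"))
  rate <- rec$rate
  half <- seconds_to_sample(window_s / 2, rate)
  n <- nrow(rec$samples)
  out <- NULL
  for (tt in event_times) {
    c0 <- seconds_to_sample(tt, rate)
    if (c0 - half < 0 || c0 + half >= n) {
      warning(sprintf("event at %.4f s too close to the recording edge; skipped", tt))
      next
    }
    # center the window on the peak of the pulse energy near the event
    search <- rec$samples[(c0 - half + 1L):(c0 + half + 1L), , drop = FALSE]
    pk <- which.max(rowSums(search^2)) + (c0 - half) - 1L
    pk <- max(half, min(n - half - 1L, pk))
    w <- rec$samples[(pk - half + 1L):(pk + half), , drop = FALSE]
    m_idx <- c(seq_len(seconds_to_sample(margin_s, rate)),
               nrow(w) - seq_len(seconds_to_sample(margin_s, rate)) + 1L)
    cen_idx <- (seconds_to_sample(center_s[1], rate) + 1L):seconds_to_sample(center_s[2], rate)
    center_rms <- apply(w[cen_idx, , drop = FALSE], 2, rms)
    ch <- which.max(center_rms)
    noise <- rms(w[m_idx, ch])
    snr <- if (noise == 0) Inf else center_rms[ch] / noise
    out <- rbind(out, data.frame(time = tt, snr = snr, channel = ch))
  }
  if (is.null(out)) out <- data.frame(time = numeric(), snr = numeric(), channel = integer())
  structure(out, class = c("vocseg_snr", "data.frame"), method = "pulse")
}

#' @rdname snr_pulse
#' @param segments data frame with `onset`/`offset` in seconds (sine song).
#' @param ann optional [annotations()] used to exclude labeled samples from
#'   the noise flanks.
#' @param flank_s flank duration (default 0.200).
#' @param buffer_s buffer between segment and flank (default 0.010).
#' @param exclude_labels annotation types excluded from the flanks.
#' @export
snr_sine <- function(rec, segments, ann = NULL, flank_s = 0.200,
                     buffer_s = 0.010, exclude_labels = c("sine", "pulse")) {
  stopifnot(inherits(rec, "vocseg_recording"))
  rate <- rec$rate
  n <- nrow(rec$samples)
  excluded <- logical(n)
  if (!is.null(ann) && nrow(ann)) {
    keep <- ann[ann$name %in% exclude_labels, , drop = FALSE]
    for (r in seq_len(nrow(keep))) {
      a <- max(0L, seconds_to_sample(keep$start_seconds[r], rate))
      b <- min(n, max(a + 1L, seconds_to_sample(keep$stop_seconds[r], rate)))
      excluded[(a + 1L):b] <- TRUE
    }
  }
  out <- NULL
  for (i in seq_len(nrow(segments))) {
    a <- seconds_to_sample(segments$onset[i], rate)
    b <- seconds_to_sample(segments$offset[i], rate)
    if (a < 0 || b > n) stop("segment outside the recording")
    sig_rms <- apply(rec$samples[(a + 1L):b, , drop = FALSE], 2, rms)
    ch <- which.max(sig_rms)
    gap <- seconds_to_sample(buffer_s, rate)
    fl <- seconds_to_sample(flank_s, rate)
    pre <- max(0L, a - gap - fl):max(0L, a - gap - 1L)
    post <- min(n - 1L, b + gap):min(n - 1L, b + gap + fl - 1L)
    fl_idx <- unique(c(pre, post)) + 1L
    fl_idx <- fl_idx[fl_idx >= 1 & fl_idx <= n & !excluded[fl_idx]]
    snr <- if (!length(fl_idx)) {
      NA_real_
    } else {
      noise <- rms(rec$samples[fl_idx, ch])
      if (noise == 0) Inf else sig_rms[ch] / noise
    }
    out <- rbind(out, data.frame(onset = segments$onset[i],
                                 offset = segments$offset[i],
                                 snr = snr, channel = ch))
  }
  if (is.null(out)) out <- data.frame(onset = numeric(), offset = numeric(),
                                      snr = numeric(), channel = integer())
  structure(out, class = c("vocseg_snr", "data.frame"), method = "sine")
}

#' @rdname snr_pulse
#' @param window_ms power-averaging window (default 1 ms).
#' @param floor_percentile percentile of windowed power used as the noise
#'   floor (default 10).
#' @export
snr_mouse <- function(rec, window_ms = 1, floor_percentile = 10) {
  stopifnot(inherits(rec, "vocseg_recording"))
  x <- rec$samples[, 1]
  w <- max(1L, seconds_to_sample(window_ms / 1000, rec$rate))
  nw <- length(x) %/% w
  if (nw < 5) stop("recording too short for windowed SNR estimation")
  pow <- colMeans(matrix(x[seq_len(nw * w)]^2, nrow = w))
  floor_pow <- stats::quantile(pow, floor_percentile / 100, names = FALSE)
  if (floor_pow <= 0) {
    warning("zero noise floor; returning Inf where signal power is positive")
    snr <- ifelse(pow > 0, Inf, 0)
  } else {
    snr <- pmax(pow - floor_pow, 0) / floor_pow
  }
  structure(data.frame(time = (seq_len(nw) - 0.5) * w / rec$rate, snr = snr),
            class = c("vocseg_snr", "data.frame"), method = "mouse")
}
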