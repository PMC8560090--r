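#' Confidence tracks
#'
#' A `vocseg_confidence` holds the per-sample, per-class softmax confidence
#' scores aligned to the audio: a `[time x classes]` matrix whose rows sum
#' to 1, the sampling rate and the class names (song types plus `"no_song"`
#' last).
#'
#' @param values numeric matrix `[time x classes]`.
#' @param rate sampling rate in Hz.
#' @param class_names column names.
#' @export
confidence_track <- function(values, rate, class_names = colnames(values)) {
  stopifnot(is.matrix(values), length(class_names) == ncol(values))
  colnames(values) <- class_names
  structure(list(values = values, rate = rate, class_names = class_names),
            class = "vocseg_confidence")
}

#' @export
print.vocseg_confidence <- function(x, ...) {
  cat(sprintf("<vocseg_confidence> %d samples @ %g Hz, classes: %s\n",
              nrow(x$values), x$rate, paste(x$class_names, collapse = ", ")))
  invisible(x)
}

# margin (in frames at the TCN rate) contaminated by zero padding on each
# side of a chunk: half the total convolutional span, plus the frames whose
# STFT window runs past the chunk end on the right
trim_frames <- function(config) {
  span <- config$tcn_stacks * (config$kernel_size - 1L) * sum(stack_dilations(config))
  half <- as.integer(ceiling(span / 2))
  fe_extra <- if (config$use_stft) {
    as.integer(ceiling((config$stft_duration - config$stft_stride) / config$stft_stride))
  } else 0L
  c(left = half, right = half + fe_extra)
}

#' Predict per-sample confidence scores
#'
#' Runs the network over a recording in overlapping chunks, discards the
#' chunk margins contaminated by zero padding (half the network's
#' convolutional span, plus the frames whose STFT window crosses the chunk
#' end), and concatenates the clean interiors; the first and last margins of
#' the recording itself are retained from the edge chunks. Because every
#' layer of the network is local in time, the result is identical to a
#' single forward pass over the whole recording.
#'
#' If the configured chunk length is too short to leave a clean interior,
#' the inference chunk is enlarged automatically (training chunk length does
#' not constrain inference).
#'
#' @param net a `vocseg_network`.
#' @param rec a [recording()] with the configured rate and channel count.
#' @param chunk_samples chunk length for inference; default taken from the
#'   network config (enlarged if needed).
#' @return a [confidence_track()] with one row per audio sample.
#' @export
predict_confidence <- function(net, rec, chunk_samples = NULL) {
  cfg <- net$config
  stopifnot(inherits(rec, "vocseg_recording"))
  if (abs(rec$rate - cfg$rate) > 1e-9) stop("recording rate does not match network config")
  if (rec$channel_count != cfg$channels) stop("channel count does not match network config")
  stride <- if (cfg$use_stft) cfg$stft_stride else 1L
  n0 <- nrow(rec$samples)
  if (n0 < receptive_field(cfg)) {
    stop("recording shorter than one receptive field")
  }
  tf <- trim_frames(cfg)

  # pad to a stride multiple; frames then tile the padded recording exactly
  pad <- (stride - n0 %% stride) %% stride
  X <- t(rec$samples)
  if (pad > 0) X <- cbind(X, matrix(0, nrow(X), pad))
  n <- ncol(X)
  n_frames <- n %/% stride

  chunk_samples <- chunk_samples %||% cfg$chunk_samples
  Lf_cfg <- max(as.integer(min(chunk_samples, n)) %/% stride, 1L)
  # keep the clean step at least twice the trimmed margin so the recompute
  # overhead from overlapping chunks stays below ~50%
  Lf_cfg <- max(Lf_cfg, 3L * sum(tf))
  step_f <- Lf_cfg - sum(tf)

  classes <- all_classes(cfg)
  if (n_frames <= Lf_cfg) {
    fwd <- network_fwd(net, X, n, want_cache = FALSE)
    prob <- softmax_cols(fwd$logits)
  } else {
    prob <- matrix(0, length(classes), n_frames)
    out_from <- 0L   # next output frame to fill (0-based)
    c0 <- 0L         # chunk start frame (0-based)
    repeat {
      last <- c0 + Lf_cfg >= n_frames
      if (last) c0 <- n_frames - Lf_cfg
      sel <- (c0 * stride + 1L):((c0 + Lf_cfg) * stride)
      fwd <- network_fwd(net, X[, sel, drop = FALSE], length(sel), want_cache = FALSE)
      p <- softmax_cols(fwd$logits)
      v_lo <- out_from            # absolute frames [v_lo, v_hi)
      v_hi <- if (last) n_frames else c0 + Lf_cfg - tf["right"]
      prob[, (v_lo + 1L):v_hi] <- p[, (v_lo - c0 + 1L):(v_hi - c0), drop = FALSE]
      out_from <- v_hi
      if (last) break
      c0 <- c0 + step_f
      # keep the next chunk's clean interior overlapping what is filled
      c0 <- min(c0, out_from - tf["left"])
    }
  }
  values <- t(prob)
  if (stride > 1L) values <- upsample_repeat(values, stride)
  values <- values[seq_len(n0), , drop = FALSE]
  confidence_track(values, cfg$rate, classes)
}

#' Detect events from a confidence track
#'
#' Event times are local maxima of one class's confidence that exceed a
#' threshold; surviving peaks are at least `min_distance` apart (higher
#' peaks kept first). Peaks on plateaus (which arise after repeat
#' upsampling) resolve to the plateau's first sample; `interpolate = TRUE`
#' additionally refines each peak by quadratic interpolation around the
#' maximum.
#'
#' @param track a [confidence_track()].
#' @param type event class name.
#' @param threshold confidence threshold in `[0, 1]` (default 0.7).
#' @param min_distance minimal distance between peaks in seconds
#'   (default 0.010).
#' @param interpolate quadratic sub-sample peak interpolation (default off).
#' @return data frame with `time` (seconds) and `confidence`, sorted by time.
#' @export
detect_events <- function(track, type, threshold = 0.7, min_distance = 0.010,
                          interpolate = FALSE) {
  if (threshold < 0 || threshold > 1) stop("threshold must be within [0, 1]")
  stopifnot(type %in% track$class_names)
  y <- track$values[, type]
  n <- length(y)
  if (n < 3) return(data.frame(time = numeric(), confidence = numeric()))

  # plateau-aware local maxima: first sample of every run that is higher
  # than the neighboring runs
  r <- label_runs(y)
  vals <- r$value
  higher_left <- c(TRUE, vals[-1] > vals[-length(vals)])
  higher_right <- c(vals[-length(vals)] > vals[-1], TRUE)
  is_peak <- higher_left & higher_right & vals >= threshold
  # runs touching the array edges only count if interior-supported
  peaks <- r$start[is_peak]
  heights <- vals[is_peak]

  if (!length(peaks)) return(data.frame(time = numeric(), confidence = numeric()))
  ord <- order(heights, decreasing = TRUE)
  min_gap <- min_distance * track$rate
  kept <- logical(0)
  kept_pos <- numeric(0)
  for (i in ord) {
    if (all(abs(peaks[i] - kept_pos) >= min_gap)) {
      kept_pos <- c(kept_pos, peaks[i])
      kept <- c(kept, i)
    }
  }
  pos <- sort(kept_pos)
  conf <- y[pos]
  time <- (pos - 1) / track$rate
  if (interpolate) {
    for (j in seq_along(pos)) {
      p <- pos[j]
      if (p > 1 && p < n) {
        den <- y[p - 1] - 2 * y[p] + y[p + 1]
        if (den < 0) {
          delta <- 0.5 * (y[p - 1] - y[p + 1]) / den
          time[j] <- time[j] + max(-1, min(1, delta)) / track$rate
        }
      }
    }
  }
  data.frame(time = time, confidence = conf)
}

#' Per-sample segment labels from confidences
#'
#' Assigns each sample the class with the highest confidence
#' (`argmax` over classes). Ties resolve to the lowest class index; since
#' `"no_song"` is ordered last, ties never silently favor it.
#'
#' @param track a [confidence_track()].
#' @return character vector of per-sample labels.
#' @export
label_segments <- function(track) {
  track$class_names[max.col(track$values, ties.method = "first")]
}

#' Smooth a per-sample label track and extract segments
#'
#' Post-processing of argmax labels: (1) `"no_song"` gaps shorter than
#' `fill_gap` between two runs of the same song label are filled with that
#' label; (2) song-label runs shorter than `min_duration` are removed
#' (relabeled `"no_song"`). The two steps are repeated until the labeling is
#' stable, so the operation is idempotent. Segment boundaries are then
#' emitted at no-song/song transitions; a segment may span several labels
#' (use [majority_vote()] to assign one).
#'
#' @param labels character vector of per-sample labels.
#' @param rate sampling rate in Hz.
#' @param fill_gap gap-filling duration in seconds (e.g. flies 0.020, mice
#'   0.010, marmosets and birds 0.005).
#' @param min_duration minimal segment duration in seconds (e.g. flies
#'   0.020, mice 0.005, marmosets and birds 0.030).
#' @param no_song_label label of the background class.
#' @return list with `labels` (smoothed track) and `segments` (data frame
#'   `onset`/`offset` in seconds, half-open).
#' @export
smooth_segments <- function(labels, rate, fill_gap = 0, min_duration = 0,
                            no_song_label = "no_song") {
  stopifnot(fill_gap >= 0, min_duration >= 0)
  fill_n <- fill_gap * rate
  min_n <- min_duration * rate
  repeat {
    before <- labels
    r <- label_runs(labels)
    if (nrow(r) >= 3) {    # step 1: fill short no-song gaps between same labels
      for (i in 2:(nrow(r) - 1L)) {
        if (r$value[i] == no_song_label && r$length[i] < fill_n &&
            r$value[i - 1L] == r$value[i + 1L] && r$value[i - 1L] != no_song_label) {
          labels[r$start[i] + seq_len(r$length[i]) - 1L] <- r$value[i - 1L]
        }
      }
    }
    r <- label_runs(labels)  # step 2: remove short song runs
    for (i in seq_len(nrow(r))) {
      if (r$value[i] != no_song_label && r$length[i] < min_n) {
        labels[r$start[i] + seq_len(r$length[i]) - 1L] <- no_song_label
      }
    }
    if (identical(labels, before)) break
  }
  r <- label_runs(labels != no_song_label)
  song <- r[r$value, , drop = FALSE]
  list(labels = labels,
       segments = data.frame(onset = (song$start - 1L) / rate,
                             offset = (song$start - 1L + song$length) / rate))
}

#' Label segments by majority vote
#'
#' Assigns each detected segment the mode of its per-sample song labels
#' (ties broken by the label occurring earliest within the segment).
#'
#' @param labels per-sample label track (the smoothed labels).
#' @param segments data frame with `onset`/`offset` in seconds, as returned
#'   by [smooth_segments()].
#' @param rate sampling rate in Hz.
#' @param no_song_label background label, excluded from the vote.
#' @return `segments` with an added `label` column.
#' @export
majority_vote <- function(labels, segments, rate, no_song_label = "no_song") {
  lab <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    a <- seconds_to_sample(segments$onset[i], rate) + 1L
    b <- seconds_to_sample(segments$offset[i], rate)
    seg <- labels[a:min(b, length(labels))]
    seg <- seg[seg != no_song_label]
    if (!length(seg)) { lab[i] <- no_song_label; next }
    counts <- table(seg)
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1L) top <- seg[seg %in% top][1L]  # earliest occurrence
    lab[i] <- top
  }
  segments$label <- lab
  segments
}

#' Convert detections to an annotation table
#'
#' Bundles detected events and labeled segments into one [annotations()]
#' table (events as `start == stop` rows).
#'
#' @param events named list of event data frames from [detect_events()]
#'   (names are the event class names).
#' @param segments labeled segment data frame from [majority_vote()].
#' @export
predictions_to_annotations <- function(events = list(), segments = NULL) {
  parts <- list()
  for (nm in names(events)) {
    if (nrow(events[[nm]])) {
      parts[[length(parts) + 1L]] <-
        data.frame(name = nm, start_seconds = events[[nm]]$time,
                   stop_seconds = events[[nm]]$time)
    }
  }
  if (!is.null(segments) && nrow(segments)) {
    parts[[length(parts) + 1L]] <-
      data.frame(name = segments$label, start_seconds = segments$onset,
                 stop_seconds = segments$offset)
  }
  if (!length(parts)) return(annotations())
  df <- do.call(rbind, parts)
  annotations(df$name, df$start_seconds, df$stop_seconds)
}
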