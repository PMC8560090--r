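#' Parameters for synthetic song elements
#'
#' Parameter bundles for the seeded song generators. Defaults follow the
#' signal statistics of *Drosophila melanogaster* courtship song: pulse song
#' is trains of short (5-10 ms) pulses with carrier frequencies between 180
#' and 500 Hz repeated at a species-specific inter-pulse interval of
#' 35-45 ms; sine song is a sustained oscillation with a species-specific
#' carrier frequency near 150 Hz.
#'
#' @param carrier_hz pulse/sine carrier frequency in Hz.
#' @param pulse_duration_ms pulse duration (Gaussian envelope support) in ms.
#' @param ipi_mean_ms,ipi_jitter_ms inter-pulse interval mean and uniform
#'   half-jitter in ms; intervals are clipped to `[35, 45]`-style bounds set
#'   by `ipi_bounds_ms`.
#' @param ipi_bounds_ms lower/upper bounds for the inter-pulse interval.
#' @param train_length number of pulses in the train.
#' @param amplitude linear peak amplitude.
#' @return A parameter list.
#' @export
pulse_train_params <- function(carrier_hz = 250, pulse_duration_ms = 7.5,
                               ipi_mean_ms = 40, ipi_jitter_ms = 5,
                               ipi_bounds_ms = c(35, 45),
                               train_length = 8L, amplitude = 1) {
  stopifnot(carrier_hz > 0, pulse_duration_ms > 0, train_length >= 1,
            ipi_mean_ms > pulse_duration_ms, amplitude >= 0)
  list(carrier_hz = carrier_hz, pulse_duration_ms = pulse_duration_ms,
       ipi_mean_ms = ipi_mean_ms, ipi_jitter_ms = ipi_jitter_ms,
       ipi_bounds_ms = ipi_bounds_ms, train_length = as.integer(train_length),
       amplitude = amplitude)
}

#' @rdname pulse_train_params
#' @param duration_ms sine-bout duration in ms.
#' @param ramp_ms onset/offset ramp duration in ms (must satisfy
#'   `duration > 2 * ramp`).
#' @export
sine_song_params <- function(carrier_hz = 150, duration_ms = 300,
                             ramp_ms = 20, amplitude = 1) {
  stopifnot(carrier_hz > 0, duration_ms > 2 * ramp_ms, amplitude >= 0)
  list(carrier_hz = carrier_hz, duration_ms = duration_ms,
       ramp_ms = ramp_ms, amplitude = amplitude)
}

#' @rdname pulse_train_params
#' @param gaussian_rms RMS of additive Gaussian background noise.
#' @param pulsatile_rate rate (events/s) of pulsatile noise transients
#'   (isolated single-cycle clicks at Poisson times, emulating e.g. fly
#'   interactions knocking the substrate).
#' @param pulsatile_amplitude peak amplitude of the noise clicks.
#' @export
noise_params <- function(gaussian_rms = 0, pulsatile_rate = 0,
                         pulsatile_amplitude = 0) {
  stopifnot(gaussian_rms >= 0, pulsatile_rate >= 0, pulsatile_amplitude >= 0)
  list(gaussian_rms = gaussian_rms, pulsatile_rate = pulsatile_rate,
       pulsatile_amplitude = pulsatile_amplitude)
}

#' Generate a synthetic pulse train
#'
#' Pulses are Gaussian-windowed cosines (Gabor-like, matching the biphasic
#' multi-cycle shape of fly song pulses) placed at jittered inter-pulse
#' intervals. The envelope standard deviation is `pulse_duration / 6` so the
#' stated duration covers +-3 sd of the envelope. Ground-truth event times
#' are the envelope peaks.
#'
#' @param params a [pulse_train_params()] list.
#' @param rate sampling rate in Hz.
#' @param seed integer seed (interval jitter); `NULL` uses the current RNG
#'   state.
#' @return list with `waveform` (numeric vector) and `event_times`
#'   (seconds, one per pulse).
#' @export
make_pulse_train <- function(params, rate, seed = NULL) {
  if (params$carrier_hz >= rate / 2) stop("carrier frequency must be below Nyquist")
  if (!is.null(seed)) set.seed(seed)
  n_p <- params$train_length
  ipi <- stats::runif(max(n_p - 1L, 0L),
                      params$ipi_mean_ms - params$ipi_jitter_ms,
                      params$ipi_mean_ms + params$ipi_jitter_ms)
  ipi <- pmin(pmax(ipi, params$ipi_bounds_ms[1]), params$ipi_bounds_ms[2])
  lead <- params$pulse_duration_ms / 1000
  event_times <- lead + c(0, cumsum(ipi)) / 1000
  n <- seconds_to_sample(max(event_times) + lead, rate) + 1L
  waveform <- numeric(n)
  sd_s <- params$pulse_duration_ms / 6 / 1000
  half <- seconds_to_sample(3 * sd_s, rate)
  for (tc in event_times) {
    c_samp <- seconds_to_sample(tc, rate)
    idx <- max(0L, c_samp - half):min(n - 1L, c_samp + half)
    tau <- idx / rate - tc
    waveform[idx + 1L] <- waveform[idx + 1L] +
      params$amplitude * exp(-tau^2 / (2 * sd_s^2)) * cos(2 * pi * params$carrier_hz * tau)
  }
  list(waveform = waveform, event_times = event_times)
}

#' Generate a synthetic sine-song bout
#'
#' A sinusoid with raised-cosine onset/offset ramps. The returned segment
#' covers the full non-zero support of the waveform.
#'
#' @inheritParams make_pulse_train
#' @param params a [sine_song_params()] list.
#' @return list with `waveform` and `segment = c(onset_s, offset_s)`.
#' @export
make_sine_song <- function(params, rate, seed = NULL) {
  if (params$carrier_hz >= rate / 2) stop("carrier frequency must be below Nyquist")
  n <- seconds_to_sample(params$duration_ms / 1000, rate)
  t <- (seq_len(n) - 1L) / rate
  w <- params$amplitude * sin(2 * pi * params$carrier_hz * t)
  n_ramp <- seconds_to_sample(params$ramp_ms / 1000, rate)
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
    w[seq_len(n_ramp)] <- w[seq_len(n_ramp)] * ramp
    w[n - n_ramp + seq_len(n_ramp)] <- w[n - n_ramp + seq_len(n_ramp)] * rev(ramp)
  }
  list(waveform = w, segment = c(0, n / rate))
}

#' Syllable templates and syllable sequences
#'
#' A syllable template describes a bird-like vocal element by its duration,
#' a frequency contour (piecewise-linear over time fractions), harmonic
#' amplitudes and an amplitude envelope with raised-cosine ramps.
#' `make_syllable_sequence()` renders `n` syllables with labels drawn from
#' the templates, separated by silent gaps, together with a ground-truth
#' annotation table.
#'
#' @param label syllable type name.
#' @param duration_ms syllable duration in ms.
#' @param contour matrix/data.frame with columns `(time_frac, hz)`; the
#'   instantaneous frequency is linearly interpolated between rows.
#' @param harmonics numeric vector of harmonic amplitudes (fundamental first).
#' @param ramp_frac fraction of the duration used for each amplitude ramp.
#' @export
syllable_template <- function(label, duration_ms, contour,
                              harmonics = 1, ramp_frac = 0.1) {
  contour <- as.matrix(contour)
  stopifnot(duration_ms > 0, ncol(contour) == 2, all(contour[, 2] > 0),
            length(harmonics) >= 1, ramp_frac >= 0, ramp_frac < 0.5)
  list(label = as.character(label), duration_ms = duration_ms,
       contour = contour, harmonics = harmonics, ramp_frac = ramp_frac)
}

render_syllable <- function(template, rate) {
  n <- seconds_to_sample(template$duration_ms / 1000, rate)
  tf <- (seq_len(n) - 0.5) / n
  f <- stats::approx(template$contour[, 1], template$contour[, 2], xout = tf,
                     rule = 2)$y
  if (max(f) * length(template$harmonics) >= rate / 2) {
    stop("syllable contour (incl. harmonics) exceeds Nyquist")
  }
  phase <- 2 * pi * cumsum(f) / rate
  w <- numeric(n)
  for (h in seq_along(template$harmonics)) {
    w <- w + template$harmonics[h] * sin(h * phase)
  }
  n_ramp <- max(1L, as.integer(round(template$ramp_frac * n)))
  ramp <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
  w[seq_len(n_ramp)] <- w[seq_len(n_ramp)] * ramp
  w[n - n_ramp + seq_len(n_ramp)] <- w[n - n_ramp + seq_len(n_ramp)] * rev(ramp)
  w / max(abs(w))
}

#' @rdname syllable_template
#' @param templates list of syllable templates.
#' @param n number of syllables to render.
#' @param gap_ms length-2 range of silent gap durations between syllables.
#' @param rate sampling rate in Hz.
#' @param seed integer seed for label and gap draws.
#' @return list with `waveform` and `annotations` (labeled segments).
#' @export
make_syllable_sequence <- function(templates, n, gap_ms = c(20, 60), rate,
                                   seed = NULL) {
  stopifnot(length(templates) >= 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(list(waveform = numeric(seconds_to_sample(0.01, rate)),
                annotations = annotations()))
  }
  picks <- sample.int(length(templates), n, replace = TRUE)
  gaps <- stats::runif(n + 1L, gap_ms[1], gap_ms[2]) / 1000
  pieces <- lapply(picks, function(i) render_syllable(templates[[i]], rate))
  total <- seconds_to_sample(sum(gaps), rate) + sum(lengths(pieces))
  waveform <- numeric(total)
  starts <- stops <- numeric(n)
  cursor <- 0L
  for (k in seq_len(n)) {
    cursor <- cursor + seconds_to_sample(gaps[k], rate)
    len <- length(pieces[[k]])
    waveform[cursor + seq_len(len)] <- pieces[[k]]
    starts[k] <- cursor / rate
    stops[k] <- (cursor + len) / rate
    cursor <- cursor + len
  }
  labels <- vapply(templates, `[[`, "", "label")[picks]
  list(waveform = waveform,
       annotations = annotations(labels, starts, stops))
}

#' Assemble a synthetic recording
#'
#' Sums placed waveform components into a (possibly multi-channel)
#' recording, adds Gaussian background noise and pulsatile noise clicks,
#' and merges the components' annotations into one sorted table. Fully
#' reproducible from the seed.
#'
#' @param components list of components, each a list with `waveform`
#'   (numeric vector), `at` (placement offset in seconds) and `annotations`
#'   (a [annotations()] table with times relative to the component start;
#'   use [events_to_annotations()] for event lists).
#' @param duration_s total recording duration in seconds.
#' @param rate sampling rate in Hz.
#' @param noise a [noise_params()] list.
#' @param channel_gains `NULL` for mono output, a numeric vector of
#'   per-channel gains applied to the summed signal, or a matrix
#'   `[n_components x n_channels]` of per-component projection gains.
#' @param seed integer seed (noise draws).
#' @param id recording id.
#' @return list with `recording` and `annotations`.
#' @export
make_recording <- function(components, duration_s, rate,
                           noise = noise_params(), channel_gains = NULL,
                           seed = NULL, id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  n <- seconds_to_sample(duration_s, rate)
  n_comp <- length(components)
  per_comp_gains <- is.matrix(channel_gains)
  if (per_comp_gains) stopifnot(nrow(channel_gains) == n_comp)

  # accumulate components in place (never materialize per-component tracks)
  acc <- if (per_comp_gains) matrix(0, n, ncol(channel_gains)) else numeric(n)
  ann_list <- list()
  for (k in seq_len(n_comp)) {
    comp <- components[[k]]
    start <- seconds_to_sample(comp$at %||% 0, rate)
    len <- length(comp$waveform)
    if (start < 0 || start + len > n) {
      stop("component ", k, " does not fit within the requested duration")
    }
    idx <- start + seq_len(len)
    if (per_comp_gains) {
      acc[idx, ] <- acc[idx, , drop = FALSE] + outer(comp$waveform, channel_gains[k, ])
    } else {
      acc[idx] <- acc[idx] + comp$waveform
    }
    ann <- comp$annotations
    if (!is.null(ann) && nrow(ann)) {
      at <- start / rate
      ann_list[[length(ann_list) + 1L]] <-
        annotations(ann$name, ann$start_seconds + at, ann$stop_seconds + at)
    }
  }
  merged <- if (length(ann_list)) do.call(rbind, lapply(ann_list, as.data.frame)) else
    as.data.frame(annotations())
  merged <- annotations(merged$name, merged$start_seconds, merged$stop_seconds)
  check_no_cross_type_overlap(merged)
  if (nrow(merged) && max(merged$stop_seconds) > duration_s + 1e-9) {
    stop("annotations extend beyond the audio")
  }

  samples <- if (per_comp_gains) {
    acc
  } else if (is.null(channel_gains)) {
    matrix(acc, ncol = 1)
  } else {
    outer(acc, as.numeric(channel_gains))
  }

  if (noise$gaussian_rms > 0) {
    samples <- samples + matrix(stats::rnorm(length(samples), sd = noise$gaussian_rms),
                                nrow = n)
  }
  if (noise$pulsatile_rate > 0 && noise$pulsatile_amplitude > 0) {
    n_clicks <- stats::rpois(1, noise$pulsatile_rate * duration_s)
    if (n_clicks > 0) {
      click_t <- sort(stats::runif(n_clicks, 0, duration_s))
      click_sign <- sample(c(-1, 1), n_clicks, replace = TRUE)
      period <- max(2L, seconds_to_sample(0.002, rate))  # 2 ms single cycle
      cyc <- noise$pulsatile_amplitude * sin(2 * pi * seq_len(period) / period)
      click_track <- numeric(n)
      for (j in seq_len(n_clicks)) {
        s0 <- seconds_to_sample(click_t[j], rate)
        idx <- s0 + seq_len(min(period, n - s0))
        if (length(idx)) click_track[idx] <- click_track[idx] + click_sign[j] * cyc[seq_along(idx)]
      }
      samples <- samples + click_track  # one click source, common to all channels
    }
  }
  list(recording = recording(samples, rate, id = id), annotations = merged)
}

check_no_cross_type_overlap <- function(ann) {
  if (nrow(ann) < 2) return(invisible(ann))
  for (i in seq_len(nrow(ann) - 1L)) {
    j <- i + 1L
    while (j <= nrow(ann) && ann$start_seconds[j] < ann$stop_seconds[i]) {
      if (ann$name[j] != ann$name[i] &&
          ann$start_seconds[j] < ann$stop_seconds[i] &&
          ann$start_seconds[i] < ann$stop_seconds[j]) {
        stop(sprintf("overlapping annotations of different types: rows %d (%s) and %d (%s)",
                     i, ann$name[i], j, ann$name[j]))
      }
      j <- j + 1L
    }
  }
  invisible(ann)
}

#' @rdname make_recording
#' @param event_times event times in seconds.
#' @param name song-type name for the events.
#' @return `events_to_annotations()` returns an [annotations()] table with
#'   `start == stop` rows.
#' @export
events_to_annotations <- function(event_times, name) {
  annotations(rep(name, length(event_times)), event_times, event_times)
}

#' Simulate a fly-like courtship song recording
#'
#' Convenience scenario used throughout the package's tests and examples:
#' alternating pulse trains and sine-song bouts separated by silent gaps on
#' a 10 kHz mono (or multi-channel) recording, with controllable background
#' noise. Pulse trains use a per-train carrier drawn from 220-280 Hz,
#' 5-10 ms pulse durations and 35-45 ms inter-pulse intervals; sine bouts
#' are 150 Hz with 0.3-1 s durations.
#'
#' @param duration_s total duration in seconds.
#' @param rate sampling rate in Hz.
#' @param noise a [noise_params()] list.
#' @param channel_gains per-channel gain vector (or `NULL` for mono).
#' @param pulse_amplitude,sine_amplitude linear peak amplitudes.
#' @param seed integer seed.
#' @param id recording id.
#' @return list with `recording` and `annotations` (classes `pulse` and
#'   `sine`).
#' @export
simulate_fly_song <- function(duration_s, rate = 10000,
                              noise = noise_params(gaussian_rms = 0.005),
                              channel_gains = NULL,
                              pulse_amplitude = 0.6, sine_amplitude = 0.3,
                              seed = 1L, id = "fly_synth") {
  set.seed(seed)
  components <- list()
  cursor <- stats::runif(1, 0.1, 0.3)
  mode_pulse <- TRUE
  while (TRUE) {
    if (mode_pulse) {
      pp <- pulse_train_params(carrier_hz = stats::runif(1, 220, 280),
                               pulse_duration_ms = stats::runif(1, 5, 10),
                               train_length = sample(4:12, 1),
                               amplitude = pulse_amplitude)
      pt <- make_pulse_train(pp, rate)
      if (cursor + length(pt$waveform) / rate > duration_s - 0.05) break
      components[[length(components) + 1L]] <- list(
        waveform = pt$waveform, at = cursor,
        annotations = events_to_annotations(pt$event_times, "pulse"))
      cursor <- cursor + length(pt$waveform) / rate + stats::runif(1, 0.2, 0.5)
    } else {
      sp <- sine_song_params(duration_ms = stats::runif(1, 300, 1000),
                             amplitude = sine_amplitude)
      ss <- make_sine_song(sp, rate)
      if (cursor + length(ss$waveform) / rate > duration_s - 0.05) break
      components[[length(components) + 1L]] <- list(
        waveform = ss$waveform, at = cursor,
        annotations = annotations("sine", ss$segment[1], ss$segment[2]))
      cursor <- cursor + length(ss$waveform) / rate + stats::runif(1, 0.2, 0.5)
    }
    mode_pulse <- !mode_pulse
  }
  make_recording(components, duration_s, rate, noise = noise,
                 channel_gains = channel_gains,
                 seed = seed + 90000L, id = id)
}
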