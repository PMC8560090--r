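#' Recording objects
#'
#' A `vocseg_recording` holds a multi-channel waveform as a numeric matrix
#' with one column per channel (`[time x channels]`), its sampling rate in
#' Hz, and an identifier. All channels have equal length and amplitudes are
#' on a nominal `[-1, 1]` scale (integer PCM is rescaled on reading).
#'
#' @param samples numeric vector (single channel) or matrix `[time x channels]`.
#' @param rate sampling rate in Hz (> 0).
#' @param id identifier string.
#' @return A `vocseg_recording` object.
#' @examples
#' rec <- recording(sin(2 * pi * 150 * seq(0, 1, by = 1e-4)), rate = 1e4)
#' duration(rec)
#' @export
recording <- function(samples, rate, id = "recording") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix [time x channels]")
  }
  assert_scalar_num(rate, "rate", min = .Machine$double.eps)
  if (nrow(samples) == 0L) stop("zero-length audio")
  structure(list(samples = samples, rate = rate,
                 channel_count = ncol(samples), id = as.character(id)),
            class = "vocseg_recording")
}

#' @rdname recording
#' @param x a `vocseg_recording`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "vocseg_recording"))
  nrow(x$samples) / x$rate
}

#' @export
print.vocseg_recording <- function(x, ...) {
  cat(sprintf("<vocseg_recording '%s'> %d channel(s), %d samples @ %g Hz (%.3f s)\n",
              x$id, x$channel_count, nrow(x$samples), x$rate, duration(x)))
  invisible(x)
}

# ---- WAV I/O ---------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer: PCM 16/24 bit and IEEE float32,
# interleaved channels. Integer PCM is rescaled to [-1, 1].

read_wav_file <- function(path) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        channels  = readBin(fmt_raw[3:4], "integer", 1L, size = 2L, endian = "little", signed = FALSE),
        rate      = readBin(fmt_raw[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1L, size = 2L, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)  # pad byte
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing fmt or data chunk): ", path)
  if (fmt$format == 65534L) fmt$format <- if (fmt$bits == 32L) 3L else 1L  # WAVE_FORMAT_EXTENSIBLE

  n_bytes <- fmt$bits %/% 8L
  n_vals <- length(data_raw) %/% n_bytes
  if (n_vals == 0L) stop("zero-length audio: ", path)
  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n_vals, size = 4L, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n_vals, size = 2L, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw[seq_len(n_vals * 3L)])
    dim(b) <- c(3L, n_vals)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)", fmt$format, fmt$bits))
  }
  n_frames <- length(x) %/% fmt$channels
  samples <- matrix(x[seq_len(n_frames * fmt$channels)], ncol = fmt$channels, byrow = TRUE)
  list(samples = samples, rate = fmt$rate)
}

write_wav_file <- function(samples, rate, path, bits = 16L) {
  stopifnot(is.matrix(samples), bits %in% c(16L, 32L))
  n_ch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- bits %/% 8L
  data_size <- length(interleaved) * n_bytes
  fmt_code <- if (bits == 32L) 3L else 1L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(n_ch, con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * n_ch * n_bytes), con, size = 4L, endian = "little")
  writeBin(as.integer(n_ch * n_bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(interleaved * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read and write audio recordings
#'
#' `load_audio()` reads a PCM (16/24 bit) or IEEE float32 WAV file into a
#' [recording()]; integer PCM samples are rescaled to `[-1, 1]`.
#' `save_audio()` writes a recording to WAV (PCM16 by default; float32
#' preserves amplitudes exactly).
#'
#' @param path path to a WAV file.
#' @param id recording identifier; defaults to the file name.
#' @param rec a `vocseg_recording`.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `load_audio()` returns a `vocseg_recording`; `save_audio()`
#'   returns `path` invisibly.
#' @export
load_audio <- function(path, id = basename(path)) {
  w <- read_wav_file(path)
  recording(w$samples, w$rate, id = id)
}

#' @rdname load_audio
#' @export
save_audio <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "vocseg_recording"))
  write_wav_file(rec$samples, rec$rate, path, bits = as.integer(bits))
}
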