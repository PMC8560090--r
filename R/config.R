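#' Network configuration
#'
#' Collects every structural hyperparameter of the sequence-labeling network:
#' sampling rate, chunk length, channel count, the optional trainable STFT
#' frontend (number of filter pairs, window length `T` and stride `s`), the
#' convolution kernels (count and duration in samples), the number of TCN
#' stacks (each a stack of `residual_per_stack` residual blocks whose
#' dilation grows as `dilation_base^(position-1)`), which stacks use
#' time-channel separable convolutions, and the song-type vocabulary.
#'
#' The class vocabulary lists the annotated song types; an implicit
#' `"no_song"` class is always appended last (see [all_classes()]). Each
#' song type has a role: `"event"` (annotated by a single time, e.g. fly
#' pulses), `"segment"` (sine song, rodent syllables) or `"syllable"`
#' (segments that additionally receive short inter-syllable gaps in the
#' training targets, as used for bird song).
#'
#' @param rate audio sampling rate in Hz.
#' @param chunk_samples chunk length in samples used for training/inference.
#' @param channels number of audio channels.
#' @param class_names character vector of song-type names (without "no_song").
#' @param class_roles roles for each class: "event", "segment" or "syllable".
#' @param use_stft logical; include the trainable STFT frontend.
#' @param stft_pairs number of cos/sin filter pairs.
#' @param stft_duration STFT window length `T` in samples.
#' @param stft_stride STFT stride `s` in samples (downsampling factor).
#' @param kernel_count number of kernels per dilated convolution.
#' @param kernel_size kernel duration in samples (at the TCN rate).
#' @param tcn_stacks number of TCN stacks.
#' @param residual_per_stack residual blocks per TCN stack (default 5).
#' @param dilation_base dilation growth factor within a stack (default 2,
#'   giving dilations 1, 2, 4, 8, 16).
#' @param separable_stacks integer indices of TCN stacks that use separable
#'   convolutions (multi-channel audio only).
#' @param skip_mode how the residual blocks' skip outputs are combined
#'   before the dense head: `"sum"` (default, parameter-economical) or
#'   `"concat"`.
#' @return A `vocseg_config` list.
#' @examples
#' cfg <- network_config(rate = 10e3, chunk_samples = 4096, channels = 1,
#'                       class_names = c("pulse", "sine"),
#'                       class_roles = c("event", "segment"))
#' receptive_field(cfg)
#' @export
network_config <- function(rate, chunk_samples, channels = 1L,
                           class_names, class_roles,
                           use_stft = FALSE, stft_pairs = 33L,
                           stft_duration = 64L, stft_stride = 16L,
                           kernel_count = 32L, kernel_size = 32L,
                           tcn_stacks = 3L, residual_per_stack = 5L,
                           dilation_base = 2L, separable_stacks = integer(),
                           skip_mode = c("sum", "concat")) {
  skip_mode <- match.arg(skip_mode)
  assert_scalar_num(rate, "rate", min = 1)
  assert_scalar_num(chunk_samples, "chunk_samples", min = 1)
  assert_scalar_num(channels, "channels", min = 1)
  assert_scalar_num(residual_per_stack, "residual_per_stack", min = 1)
  stopifnot(length(class_names) >= 1, length(class_roles) == length(class_names))
  if (!all(class_roles %in% c("event", "segment", "syllable"))) {
    stop("class_roles must be 'event', 'segment' or 'syllable'")
  }
  if ("no_song" %in% class_names) stop("'no_song' is implicit; do not list it")
  if (use_stft) {
    if (chunk_samples %% stft_stride != 0) {
      stop("chunk_samples must be a positive multiple of stft_stride")
    }
    if (stft_pairs > stft_duration %/% 2 + 1) {
      stop("stft_pairs must be <= T/2 + 1")
    }
  }
  if (length(separable_stacks) && any(separable_stacks < 1 | separable_stacks > tcn_stacks)) {
    stop("separable_stacks indices out of range")
  }
  structure(list(
    rate = rate, chunk_samples = as.integer(chunk_samples),
    channels = as.integer(channels),
    class_names = as.character(class_names), class_roles = as.character(class_roles),
    use_stft = isTRUE(use_stft), stft_pairs = as.integer(stft_pairs),
    stft_duration = as.integer(stft_duration), stft_stride = as.integer(stft_stride),
    kernel_count = as.integer(kernel_count), kernel_size = as.integer(kernel_size),
    tcn_stacks = as.integer(tcn_stacks),
    residual_per_stack = as.integer(residual_per_stack),
    dilation_base = as.integer(dilation_base),
    separable_stacks = as.integer(separable_stacks),
    skip_mode = skip_mode
  ), class = "vocseg_config")
}

#' @rdname network_config
#' @param config a `vocseg_config`.
#' @return `all_classes()` returns the output class names: the song types
#'   followed by `"no_song"`.
#' @export
all_classes <- function(config) c(config$class_names, "no_song")

# dilations of one TCN stack, e.g. 1 2 4 8 16
stack_dilations <- function(config) {
  config$dilation_base^(seq_len(config$residual_per_stack) - 1L)
}

#' Receptive field of a configured network
#'
#' Span of input influencing one output sample:
#' `1 + sum over all dilated convolutions of (kernel_size - 1) * dilation`,
#' multiplied by the frontend stride when the STFT frontend is present
#' (the convolutions then operate on downsampled frames). Used to size the
#' chunk overlap during chunked inference.
#'
#' @param config a `vocseg_config`.
#' @return receptive field in samples.
#' @export
receptive_field <- function(config) {
  per_stack <- (config$kernel_size - 1L) * sum(stack_dilations(config))
  rf <- 1L + config$tcn_stacks * per_stack
  if (config$use_stft) rf <- rf * config$stft_stride
  as.integer(rf)
}

#' @export
print.vocseg_config <- function(x, ...) {
  cat(sprintf("<vocseg_config> %g Hz, %d ch, chunk %d | %s | %d stacks x %d blocks, %d kernels of %d samples | classes: %s\n",
              x$rate, x$channels, x$chunk_samples,
              if (x$use_stft) sprintf("STFT %d pairs T=%d s=%d", x$stft_pairs, x$stft_duration, x$stft_stride) else "no STFT",
              x$tcn_stacks, x$residual_per_stack, x$kernel_count, x$kernel_size,
              paste(all_classes(x), collapse = ", ")))
  invisible(x)
}

#' Species presets
#'
#' Structural presets for the species families the method has been used on,
#' shipped as YAML files under `inst/presets/`. Each preset bundles a
#' [network_config()] plus post-processing defaults (event threshold and
#' minimal peak distance, segment gap-fill and minimum duration) and the
#' evaluation tolerance. Available presets: `fly_single`, `fly_multi_pulse`,
#' `fly_multi_sine`, `mouse`, `marmoset`, `bengalese_finch`, `zebra_finch`.
#'
#' @param name preset name.
#' @return A list with elements `config` (a `vocseg_config`), `postprocess`
#'   and `training`.
#' @examples
#' p <- load_preset("fly_single")
#' p$config$tcn_stacks
#' @export
load_preset <- function(name) {
  path <- system.file("presets", paste0(name, ".yaml"), package = "vocseg")
  if (path == "") {
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  }
  read_config(path)
}

#' @rdname load_preset
#' @export
preset_names <- function() {
  sub("\\.yaml$", "", list.files(system.file("presets", package = "vocseg"),
                                 pattern = "\\.yaml$"))
}

#' Read and write configuration files
#'
#' Serializes a network configuration (plus optional post-processing and
#' training sections) to YAML and back.
#'
#' @param path YAML file path.
#' @param preset list as returned by [load_preset()], or a bare
#'   `vocseg_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- y$config %||% y
  config <- network_config(
    rate = cfg$rate, chunk_samples = cfg$chunk_samples,
    channels = cfg$channels %||% 1L,
    class_names = unlist(cfg$class_names),
    class_roles = unlist(cfg$class_roles),
    use_stft = isTRUE(cfg$use_stft),
    stft_pairs = cfg$stft_pairs %||% 33L,
    stft_duration = cfg$stft_duration %||% 64L,
    stft_stride = cfg$stft_stride %||% 16L,
    kernel_count = cfg$kernel_count %||% 32L,
    kernel_size = cfg$kernel_size %||% 32L,
    tcn_stacks = cfg$tcn_stacks %||% 3L,
    residual_per_stack = cfg$residual_per_stack %||% 5L,
    dilation_base = cfg$dilation_base %||% 2L,
    separable_stacks = unlist(cfg$separable_stacks) %||% integer(),
    skip_mode = cfg$skip_mode %||% "sum"
  )
  list(config = config,
       postprocess = y$postprocess %||% list(),
       training = y$training %||% list())
}

#' @rdname read_config
#' @export
write_config <- function(preset, path) {
  if (inherits(preset, "vocseg_config")) preset <- list(config = preset)
  out <- preset
  out$config <- unclass(preset$config)
  yaml::write_yaml(out, path)
  invisible(path)
}
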