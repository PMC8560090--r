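#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert seconds to sample indices and back
#'
#' All time/sample conversions in the package go through these helpers.
#' Sample indexing is 0-based; `seconds_to_sample(t, rate)` returns
#' `round(t * rate)` so that converting back with [sample_to_seconds()] is
#' accurate to within half a sample period.
#'
#' @param seconds numeric vector of times in seconds.
#' @param sample numeric vector of 0-based sample indices.
#' @param rate sampling rate in Hz.
#' @return integer sample indices (0-based), or times in seconds.
#' @export
seconds_to_sample <- function(seconds, rate) {
  stopifnot(rate > 0)
  as.integer(round(seconds * rate))
}

#' @rdname seconds_to_sample
#' @export
sample_to_seconds <- function(sample, rate) {
  stopifnot(rate > 0)
  sample / rate
}

#' Root-mean-square amplitude
#'
#' Defined as `sqrt(mean(x^2))`.
#'
#' @param x numeric vector.
#' @return scalar RMS value.
#' @export
rms <- function(x) sqrt(mean(x^2))

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# run-length helper returning start indices (1-based), lengths and values
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, length = r$lengths,
             value = r$values, stringsAsFactors = FALSE)
}
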