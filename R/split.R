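#' Split recordings into train/validation/test sets
#'
#' Each recording is split by duration into a training, validation and test
#' portion (default fractions 80:10:10; 60:20:20 is used for repertoires
#' whose call types are unevenly distributed in time). The validation and
#' test blocks are contiguous and placed, per recording, at a position drawn
#' uniformly from the first, the middle or the last part of the recording;
#' the two blocks get distinct positions. The training set is the remainder.
#'
#' Intervals are half-open `[start, stop)` in 0-based samples; per recording
#' they are disjoint and their union covers every sample exactly once.
#'
#' @param recordings list of [recording()] objects (or a single recording).
#' @param fractions numeric triple (train, val, test), positive-or-zero,
#'   summing to 1.
#' @param position_seed integer seed for the position draws.
#' @param share_positions if `TRUE`, one position draw is shared by all
#'   recordings instead of re-drawing per recording.
#' @return A `vocseg_split`: list with one element per recording
#'   (`id`, `n_samples`, and `train`/`val`/`test` interval matrices with
#'   columns `start`, `stop`), plus the fractions used.
#' @examples
#' rec <- recording(rnorm(10000), rate = 1000)
#' sp <- split_dataset(list(rec), c(0.8, 0.1, 0.1), position_seed = 1)
#' sp$recordings[[1]]$val
#' @export
split_dataset <- function(recordings, fractions = c(0.8, 0.1, 0.1),
                          position_seed = 1L, share_positions = FALSE) {
  if (inherits(recordings, "vocseg_recording")) recordings <- list(recordings)
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(position_seed)
  shared <- if (share_positions) draw_positions() else NULL

  entries <- lapply(recordings, function(rec) {
    stopifnot(inherits(rec, "vocseg_recording"))
    n <- nrow(rec$samples)
    val_len <- as.integer(round(n * fractions[2]))
    test_len <- as.integer(round(n * fractions[3]))
    if ((fractions[2] > 0 && val_len == 0L) || (fractions[3] > 0 && test_len == 0L)) {
      stop("recording '", rec$id, "' is shorter than the smallest requested block")
    }
    pos <- if (share_positions) shared else draw_positions()
    val <- place_block(n, val_len, pos[1])
    test <- place_block(n, test_len, pos[2])
    if (nrow(val) && nrow(test) &&
        val[1, "start"] < test[1, "stop"] && test[1, "start"] < val[1, "stop"]) {
      stop("val and test fractions too large for disjoint blocks in '", rec$id, "'")
    }
    train <- interval_complement(n, rbind(val, test))
    list(id = rec$id, n_samples = n, train = train, val = val, test = test)
  })
  structure(list(recordings = entries, fractions = fractions),
            class = "vocseg_split")
}

draw_positions <- function() sample(c("first", "middle", "last"), 2L)

place_block <- function(n, len, where) {
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "stop")))
  if (len == 0L) return(empty)
  if (len > n) stop("block longer than recording")
  start <- switch(where,
                  first = 0L,
                  middle = as.integer((n - len) %/% 2L),
                  last = as.integer(n - len))
  matrix(c(start, start + len), ncol = 2, dimnames = list(NULL, c("start", "stop")))
}

# complement of a set of disjoint [start, stop) intervals within [0, n)
interval_complement <- function(n, blocks) {
  if (!nrow(blocks)) {
    return(matrix(c(0L, n), ncol = 2, dimnames = list(NULL, c("start", "stop"))))
  }
  blocks <- blocks[order(blocks[, "start"]), , drop = FALSE]
  out <- NULL
  cur <- 0L
  for (i in seq_len(nrow(blocks))) {
    if (blocks[i, "start"] > cur) out <- rbind(out, c(cur, blocks[i, "start"]))
    cur <- max(cur, blocks[i, "stop"])
  }
  if (cur < n) out <- rbind(out, c(cur, n))
  if (is.null(out)) out <- matrix(integer(), ncol = 2)
  colnames(out) <- c("start", "stop")
  out
}

#' @export
print.vocseg_split <- function(x, ...) {
  cat(sprintf("<vocseg_split> %d recording(s), fractions %s\n",
              length(x$recordings), paste(x$fractions, collapse = ":")))
  invisible(x)
}
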