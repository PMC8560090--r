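#' Annotation tables
#'
#' Annotations are a data frame with columns `name` (song type),
#' `start_seconds` and `stop_seconds`. Segment-like song (sine song,
#' syllables) has `stop > start`; event-like song (pulses) is encoded with
#' `start == stop`. Rows are kept sorted by start time.
#'
#' @param name character vector of song-type names.
#' @param start_seconds,stop_seconds numeric vectors of interval bounds in
#'   seconds; events use `start == stop`.
#' @return A data frame of class `vocseg_annotations`, sorted by start.
#' @examples
#' ann <- annotations(c("pulse", "sine"), c(0.1, 0.2), c(0.1, 0.5))
#' is_event(ann)
#' @export
annotations <- function(name = character(), start_seconds = numeric(),
                        stop_seconds = numeric()) {
  df <- data.frame(name = as.character(name),
                   start_seconds = as.numeric(start_seconds),
                   stop_seconds = as.numeric(stop_seconds),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
  df <- df[order(df$start_seconds, df$stop_seconds), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("vocseg_annotations", "data.frame")
  df
}

validate_annotations <- function(df) {
  required <- c("name", "start_seconds", "stop_seconds")
  if (!all(required %in% names(df))) {
    stop("annotations need columns: ", paste(required, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) stop("unknown annotation columns: ", paste(extra, collapse = ", "))
  bad <- which(df$stop_seconds < df$start_seconds)
  if (length(bad)) {
    stop(sprintf("stop < start in annotation row(s) %s", paste(bad, collapse = ", ")))
  }
  invisible(df)
}

#' @rdname annotations
#' @param ann a `vocseg_annotations` table.
#' @return `is_event()` returns a logical vector marking rows with
#'   `start == stop`.
#' @export
is_event <- function(ann) ann$stop_seconds == ann$start_seconds

#' Read and write annotation CSV files
#'
#' The on-disk dialect is a UTF-8 CSV with a header row and columns
#' `name,start_seconds,stop_seconds`. Events are rows with
#' `start_seconds == stop_seconds`. Reading sorts rows by start time and
#' validates intervals; writing is the exact inverse, so a write/read
#' round-trip is the identity on valid tables.
#'
#' @param path CSV file path.
#' @param ann a `vocseg_annotations` table.
#' @return `read_annotations()` returns a `vocseg_annotations` table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  extra <- setdiff(names(df), c("name", "start_seconds", "stop_seconds"))
  if (length(extra)) {
    stop("unknown annotation columns in ", path, ": ", paste(extra, collapse = ", "))
  }
  annotations(df$name %||% stop("missing column `name` in ", path),
              df$start_seconds %||% stop("missing column `start_seconds` in ", path),
              df$stop_seconds %||% stop("missing column `stop_seconds` in ", path))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
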