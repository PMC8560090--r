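#' Tolerance-based event matching
#'
#' Matches predicted event times to true event times: every prediction is
#' paired with a true event within `tolerance`; when several predictions
#' compete for the same true event only the nearest becomes a true positive
#' and the others are re-matched to remaining true events within tolerance
#' or counted as false positives. Implemented as greedy matching in
#' ascending pair distance, which realizes exactly that rule: at most one
#' true positive per true event, unmatched predictions are false positives,
#' unmatched true events are false negatives.
#'
#' @param true_times,predicted_times numeric vectors of event times in
#'   seconds (sorted or not).
#' @param tolerance maximal matching distance in seconds (> 0).
#' @return list of class `vocseg_counts` with `TP`, `FP`, `FN`, `TN`
#'   (`NA` unless set from [pseudo_true_negatives()]) and `matched_pairs`
#'   (data frame `true`/`predicted`).
#' @export
match_events <- function(true_times, predicted_times, tolerance) {
  stopifnot(tolerance > 0)
  true_times <- sort(as.numeric(true_times))
  predicted_times <- sort(as.numeric(predicted_times))
  nt <- length(true_times); np <- length(predicted_times)

  pairs <- NULL
  if (nt && np) {
    j0 <- 1L
    for (i in seq_len(np)) {
      p <- predicted_times[i]
      while (j0 <= nt && true_times[j0] < p - tolerance) j0 <- j0 + 1L
      j <- j0
      while (j <= nt && true_times[j] <= p + tolerance) {
        pairs <- rbind(pairs, c(i, j, abs(p - true_times[j])))
        j <- j + 1L
      }
    }
  }
  matched <- matrix(numeric(), ncol = 2)
  used_p <- logical(np); used_t <- logical(nt)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- used_t[j] <- TRUE
        matched <- rbind(matched, c(true_times[j], predicted_times[i]))
      }
    }
  }
  structure(list(TP = sum(used_t), FP = np - sum(used_p), FN = nt - sum(used_t),
                 TN = NA_real_,
                 matched_pairs = data.frame(true = matched[, 1],
                                            predicted = matched[, 2])),
            class = "vocseg_counts")
}

#' Pseudo true negatives for event classes
#'
#' Estimated as the number of `2 * tolerance` windows fitting into the
#' recording minus the number of true events, clipped at zero. Only used to
#' fill confusion matrices / accuracy; precision, recall and F1 are
#' unaffected.
#'
#' @param duration recording duration in seconds (> 0).
#' @param tolerance matching tolerance in seconds.
#' @param n_true number of true events.
#' @return integer count.
#' @export
pseudo_true_negatives <- function(duration, tolerance, n_true) {
  stopifnot(duration > 0, tolerance > 0)
  max(0L, as.integer(floor(duration / (2 * tolerance))) - as.integer(n_true))
}

#' Precision, recall, F1 and accuracy from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, and — when true
#' negatives are available — `accuracy = (TP+TN)/(TP+TN+FP+FN)`. Undefined
#' 0/0 ratios return 0 with a warning.
#'
#' @param counts a `vocseg_counts` from [match_events()].
#' @param tn optional (pseudo) true-negative count.
#' @return list of class `vocseg_metrics` with `precision`, `recall`, `f1`,
#'   `accuracy`, `temporal_error_median` (seconds) and the counts.
#' @export
event_metrics <- function(counts, tn = counts$TN) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); returning 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  p <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  r <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  acc <- if (is.na(tn)) NA_real_ else
    (counts$TP + tn) / (counts$TP + tn + counts$FP + counts$FN)
  structure(list(precision = p, recall = r, f1 = f1, accuracy = acc,
                 temporal_error_median = if (nrow(counts$matched_pairs)) {
                   temporal_error(counts$matched_pairs)
                 } else NA_real_,
                 counts = counts),
            class = "vocseg_metrics")
}

#' @export
print.vocseg_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f%s%s\n",
              x$precision, x$recall, x$f1,
              if (!is.na(x$accuracy)) sprintf("  accuracy %.3f", x$accuracy) else "",
              if (!is.na(x$temporal_error_median))
                sprintf("  temporal error %.2f ms", 1000 * x$temporal_error_median) else ""))
  invisible(x)
}

#' Temporal precision of matched events
#'
#' Median absolute distance between matched true and predicted event times.
#'
#' @param matched_pairs data frame with columns `true` and `predicted`.
#' @return median absolute error in seconds; `NA` for no pairs.
#' @export
temporal_error <- function(matched_pairs) {
  if (!nrow(matched_pairs)) return(NA_real_)
  stats::median(abs(matched_pairs$true - matched_pairs$predicted))
}

#' Confusion matrix for segment labels
#'
#' In `"sample"` mode, the true and predicted per-sample label tracks are
#' compared sample by sample. In `"syllable"` mode one comparison is made
#' per detected segment: the mode of the true labels and the mode of the
#' predicted labels over the segment's samples (reference direction
#' selectable via `segments` taken from the detections or from the truth).
#'
#' @param true_labels,predicted_labels per-sample label vectors (equal
#'   length), from a shared vocabulary.
#' @param mode `"sample"` or `"syllable"`.
#' @param segments for syllable mode: data frame `onset`/`offset` (seconds).
#' @param rate sampling rate (syllable mode).
#' @param no_song_label background label.
#' @return list with `confusion` (true classes in rows, predicted in
#'   columns), `accuracy`, and `per_class` precision/recall/F1.
#' @export
segment_confusion <- function(true_labels, predicted_labels,
                              mode = c("sample", "syllable"),
                              segments = NULL, rate = NULL,
                              no_song_label = "no_song") {
  mode <- match.arg(mode)
  vocab <- sort(unique(c(true_labels, predicted_labels, no_song_label)))
  vocab <- c(setdiff(vocab, no_song_label), no_song_label)
  if (mode == "sample") {
    if (length(true_labels) != length(predicted_labels)) {
      stop("label tracks must have equal length")
    }
    tl <- factor(true_labels, levels = vocab)
    pl <- factor(predicted_labels, levels = vocab)
  } else {
    stopifnot(!is.null(segments), !is.null(rate))
    seg_mode <- function(lab) {
      vapply(seq_len(nrow(segments)), function(i) {
        a <- seconds_to_sample(segments$onset[i], rate) + 1L
        b <- min(seconds_to_sample(segments$offset[i], rate), length(lab))
        v <- lab[a:b]
        v <- v[v != no_song_label]
        if (!length(v)) return(no_song_label)
        counts <- table(v)
        top <- names(counts)[counts == max(counts)]
        if (length(top) > 1L) top <- v[v %in% top][1L]
        top
      }, "")
    }
    tl <- factor(seg_mode(true_labels), levels = vocab)
    pl <- factor(seg_mode(predicted_labels), levels = vocab)
  }
  cm <- table(true = tl, predicted = pl)
  acc <- sum(diag(cm)) / max(sum(cm), 1)
  per_class <- lapply(vocab, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    list(precision = p, recall = r,
         f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
  })
  names(per_class) <- vocab
  list(confusion = cm, accuracy = acc, per_class = per_class)
}

#' Sequence error rate (normalized edit distance)
#'
#' Minimal number of insertions, deletions and substitutions needed to turn
#' the true syllable-label sequence into the predicted one, normalized by
#' the length of the true sequence (Levenshtein distance / length).
#'
#' @param true_seq,pred_seq character vectors of syllable labels.
#' @return non-negative fraction (can exceed 1).
#' @export
sequence_error_rate <- function(true_seq, pred_seq) {
  if (!length(true_seq)) stop("true sequence must be non-empty")
  levenshtein(true_seq, pred_seq) / length(true_seq)
}

# dynamic-programming Levenshtein distance over label vectors
levenshtein <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na) return(nb)
  if (!nb) return(na)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1L)
    cur[1] <- i
    sub <- prev[1:nb] + (a[i] != b)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- min(cur[j] + 1, prev[j + 1L] + 1, sub[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}
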