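#' Encode annotations as sample-wise training targets
#'
#' Builds the `[time x classes]` target matrix for a recording. Segment
#' classes are binary on `[start, stop)`. Event classes become unit-peak
#' Gaussian bumps (standard deviation `event_sigma_ms`, truncated at four
#' standard deviations) centered on the event sample, encoding uncertainty
#' in the event time. For classes with the `"syllable"` role, a short
#' `"no_song"` gap of `syllable_gap_ms` is relabeled between adjacent
#' syllables so that on- and offsets are unambiguous changes from no-song to
#' song. The final `"no_song"` class completes every row to 1; where song
#' values overlap (e.g. bump tails reaching into a neighboring segment) the
#' song entries are renormalized proportionally first, so every row sums to
#' exactly 1.
#'
#' @param ann a [annotations()] table.
#' @param n_samples number of samples of the recording.
#' @param rate sampling rate in Hz.
#' @param class_names song-type names (the target columns, before "no_song").
#' @param class_roles per-class roles: "event", "segment" or "syllable".
#' @param event_sigma_ms bump standard deviation in ms (default 1.6).
#' @param syllable_gap_ms inter-syllable gap in ms (default 6.25, i.e. 200
#'   samples at 32 kHz).
#' @return numeric matrix `[n_samples x (classes + 1)]` with column names
#'   `c(class_names, "no_song")`; every row sums to 1.
#' @examples
#' ann <- annotations("pulse", 0.05, 0.05)
#' tm <- encode_targets(ann, 1000, 10000, "pulse", "event")
#' range(rowSums(tm))
#' @export
encode_targets <- function(ann, n_samples, rate, class_names, class_roles,
                           event_sigma_ms = 1.6, syllable_gap_ms = 6.25) {
  stopifnot(length(class_names) == length(class_roles), n_samples >= 1)
  unknown <- setdiff(unique(ann$name), class_names)
  if (length(unknown)) {
    stop("annotation types not in the class vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  seg_rows <- ann[!is_event(ann), , drop = FALSE]
  check_no_cross_type_overlap(seg_rows)

  n_cls <- length(class_names)
  M <- matrix(0, n_samples, n_cls, dimnames = list(NULL, class_names))

  for (ci in seq_len(n_cls)) {
    rows <- ann[ann$name == class_names[ci], , drop = FALSE]
    if (!nrow(rows)) next
    if (class_roles[ci] == "event") {
      sigma <- event_sigma_ms / 1000 * rate
      half <- as.integer(ceiling(4 * sigma))
      for (tt in rows$start_seconds) {
        ctr <- seconds_to_sample(tt, rate)
        idx <- max(0L, ctr - half):min(n_samples - 1L, ctr + half)
        M[idx + 1L, ci] <- M[idx + 1L, ci] + exp(-(idx - ctr)^2 / (2 * sigma^2))
      }
    } else {
      for (r in seq_len(nrow(rows))) {
        a <- seconds_to_sample(rows$start_seconds[r], rate)
        b <- seconds_to_sample(rows$stop_seconds[r], rate)
        a <- max(a, 0L); b <- min(b, n_samples)
        if (b > a) M[(a + 1L):b, ci] <- 1
      }
    }
  }

  # inter-syllable gaps: relabel a short no-song window at the boundary
  # between adjacent syllable-role segments
  syl_classes <- class_names[class_roles == "syllable"]
  if (length(syl_classes)) {
    syl <- ann[ann$name %in% syl_classes & !is_event(ann), , drop = FALSE]
    if (nrow(syl) > 1) {
      gap_samp <- as.integer(round(syllable_gap_ms / 1000 * rate))
      syl <- syl[order(syl$start_seconds), , drop = FALSE]
      for (r in seq_len(nrow(syl) - 1L)) {
        gap_s <- syl$start_seconds[r + 1L] - syl$stop_seconds[r]
        if (gap_s * rate < gap_samp) {
          mid <- seconds_to_sample((syl$stop_seconds[r] + syl$start_seconds[r + 1L]) / 2, rate)
          a <- max(0L, mid - gap_samp %/% 2L)
          b <- min(n_samples, a + gap_samp)
          if (b > a) M[(a + 1L):b, class_names %in% syl_classes] <- 0
        }
      }
    }
  }

  s <- rowSums(M)
  over <- s > 1
  if (any(over)) M[over, ] <- M[over, , drop = FALSE] / s[over]
  cbind(M, no_song = 1 - pmin(s, 1))
}

# frame-rate targets: mean of the sample-rate targets within each stride
# group (rows still sum to 1)
downsample_targets <- function(Tm, stride) {
  if (stride == 1L) return(Tm)
  n <- nrow(Tm)
  stopifnot(n %% stride == 0L)
  nf <- n %/% stride
  out <- matrix(0, nf, ncol(Tm), dimnames = list(NULL, colnames(Tm)))
  for (j in seq_len(ncol(Tm))) {
    out[, j] <- colMeans(matrix(Tm[, j], nrow = stride))
  }
  out
}

#' Training configuration
#'
#' @param batch_size chunks per optimizer step (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_epochs maximum training epochs (default 400).
#' @param patience early stopping: stop when the validation loss has not
#'   improved for this many epochs (default 20); the best-validation weights
#'   are restored.
#' @param event_sigma_ms,syllable_gap_ms target-encoding parameters, see
#'   [encode_targets()].
#' @param class_weights optional per-class loss weights (length classes + 1,
#'   "no_song" last); `NULL` (default) trains unweighted; `"inverse"`
#'   weights classes by inverse frequency in the training targets.
#' @param seed integer seed for chunk shuffling/offsets.
#' @return list of class `vocseg_train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         max_epochs = 400L, patience = 20L,
                         event_sigma_ms = 1.6, syllable_gap_ms = 6.25,
                         class_weights = NULL, seed = 1L) {
  stopifnot(patience <= max_epochs, learning_rate >= 0, batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 event_sigma_ms = event_sigma_ms,
                 syllable_gap_ms = syllable_gap_ms,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "vocseg_train_config")
}

adam_new <- function(flat) {
  list(m = lapply(flat, function(p) p * 0), v = lapply(flat, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, flat, grads, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g * g
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + state$eps)
  }
  list(state = state, flat = flat)
}

# enumerate training chunks: (recording index, start sample) pairs fully
# inside the given intervals, starting at `offset` samples into each interval
chunk_starts <- function(entries, chunk, which_set, offset = 0L) {
  out <- NULL
  for (ri in seq_along(entries)) {
    iv <- entries[[ri]][[which_set]]
    for (r in seq_len(nrow(iv))) {
      lo <- iv[r, "start"] + offset
      while (lo + chunk <= iv[r, "stop"]) {
        out <- rbind(out, c(ri, lo))
        lo <- lo + chunk
      }
    }
  }
  out
}

batch_tensors <- function(net, recordings, targets, chunk_list, stride) {
  cfg <- net$config
  chunk <- cfg$chunk_samples
  B <- nrow(chunk_list)
  X <- matrix(0, cfg$channels, B * chunk)
  Tm <- NULL
  for (b in seq_len(B)) {
    ri <- chunk_list[b, 1]; s0 <- chunk_list[b, 2]
    X[, (b - 1L) * chunk + seq_len(chunk)] <-
      t(recordings[[ri]]$samples[s0 + seq_len(chunk), , drop = FALSE])
    tgt <- targets[[ri]][s0 + seq_len(chunk), , drop = FALSE]
    if (stride > 1L) tgt <- downsample_targets(tgt, stride)
    Tm <- cbind(Tm, t(tgt))
  }
  list(X = X, Tm = Tm)
}

#' Train a network
#'
#' Fits the network with the Adam optimizer on the categorical cross-entropy
#' between the softmax confidences and the encoded targets. Audio is cut
#' into chunks of `config$chunk_samples`; training chunks are drawn from the
#' split's train intervals with a per-epoch random offset (so chunk
#' boundaries do not align with annotation boundaries), shuffled, and
#' processed in batches. After every epoch the validation loss is computed
#' on fixed validation chunks; training stops after `max_epochs` or earlier
#' when the validation loss has not improved for `patience` epochs, and the
#' weights of the best validation epoch are restored.
#'
#' @param net a `vocseg_network` from [build_network()].
#' @param recordings list of [recording()] objects.
#' @param annotation_tables list of [annotations()] tables, one per recording.
#' @param split a [split_dataset()] result for the same recordings.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with `net` (trained network) and `history` (data frame of
#'   per-epoch train/val loss).
#' @export
train_network <- function(net, recordings, annotation_tables, split,
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "vocseg_network"),
            length(recordings) == length(annotation_tables),
            length(recordings) == length(split$recordings))
  cfg <- net$config
  stride <- if (cfg$use_stft) cfg$stft_stride else 1L
  for (rec in recordings) {
    if (abs(rec$rate - cfg$rate) > 1e-9) stop("recording rate does not match network config")
  }
  targets <- lapply(seq_along(recordings), function(i) {
    encode_targets(annotation_tables[[i]], nrow(recordings[[i]]$samples),
                   cfg$rate, cfg$class_names, cfg$class_roles,
                   event_sigma_ms = config$event_sigma_ms,
                   syllable_gap_ms = config$syllable_gap_ms)
  })

  class_weights <- config$class_weights
  if (identical(class_weights, "inverse")) {
    freq <- Reduce(`+`, lapply(targets, colSums))
    class_weights <- sum(freq) / (length(freq) * pmax(freq, 1))
  }

  val_chunks <- chunk_starts(split$recordings, cfg$chunk_samples, "val")
  train_probe <- chunk_starts(split$recordings, cfg$chunk_samples, "train")
  if (is.null(train_probe)) stop("empty training split (no full chunk fits)")

  flat <- collect_params(net)
  opt <- adam_new(flat)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  history <- NULL
  set.seed(config$seed)

  eval_loss <- function(net, chunks) {
    if (is.null(chunks)) return(NA_real_)
    tot <- 0; nfr <- 0
    for (b in seq_len(nrow(chunks))) {
      bt <- batch_tensors(net, recordings, targets, chunks[b, , drop = FALSE], stride)
      fwd <- network_fwd(net, bt$X, cfg$chunk_samples, want_cache = FALSE)
      sx <- softmax_xent(fwd$logits, bt$Tm, class_weights)
      tot <- tot + sx$loss * ncol(bt$Tm)
      nfr <- nfr + ncol(bt$Tm)
    }
    tot / nfr
  }

  for (epoch in seq_len(config$max_epochs)) {
    offset <- sample.int(cfg$chunk_samples, 1L) - 1L
    if (stride > 1L) offset <- (offset %/% stride) * stride
    chunks <- chunk_starts(split$recordings, cfg$chunk_samples, "train", offset)
    if (is.null(chunks)) chunks <- train_probe
    chunks <- chunks[sample.int(nrow(chunks)), , drop = FALSE]
    ep_loss <- 0; ep_frames <- 0
    for (b0 in seq(1L, nrow(chunks), by = config$batch_size)) {
      sel <- chunks[b0:min(b0 + config$batch_size - 1L, nrow(chunks)), , drop = FALSE]
      bt <- batch_tensors(net, recordings, targets, sel, stride)
      fwd <- network_fwd(net, bt$X, cfg$chunk_samples, want_cache = TRUE)
      sx <- softmax_xent(fwd$logits, bt$Tm, class_weights)
      if (!is.finite(sx$loss)) {
        stop(sprintf("training aborted: non-finite loss at epoch %d (learning rate too high?)", epoch))
      }
      grads <- network_bwd(net, fwd, sx$dZ)
      gflat <- collect_grads(net, grads)
      st <- adam_step(opt, flat, gflat, config$learning_rate)
      opt <- st$state; flat <- st$flat
      net <- assign_params(net, flat)
      ep_loss <- ep_loss + sx$loss * ncol(bt$Tm)
      ep_frames <- ep_frames + ncol(bt$Tm)
    }
    train_loss <- ep_loss / ep_frames
    val_loss <- eval_loss(net, val_chunks)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
    }
    monitor <- if (is.na(val_loss)) train_loss else val_loss
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, flat = flat, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  net <- assign_params(net, best$flat)
  list(net = net, history = history, best_epoch = best$epoch)
}
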