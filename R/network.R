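#' Build the sequence-labeling network
#'
#' Constructs the model described by a [network_config()]: an optional
#' trainable STFT frontend (cos/sin kernel banks initialized as DFT kernels),
#' `tcn_stacks` TCN stacks of `residual_per_stack` residual blocks each
#' (dilated convolution, rectifier, max-abs normalization, residual add),
#' with the dilation doubling within each stack (1, 2, 4, 8, 16 for five
#' blocks), a skip path that sums every residual block's output, and a
#' per-frame dense layer with softmax over the song types plus `"no_song"`.
#' When the frontend downsamples by its stride, confidence scores are
#' restored to the audio rate by repeating values ([upsample_repeat()]).
#'
#' Weights use fan-based uniform (Glorot) initialization under the given
#' seed, except the frontend kernels which start as exact DFT filters.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return A `vocseg_network` object.
#' @examples
#' cfg <- network_config(rate = 1000, chunk_samples = 256, channels = 1,
#'                       class_names = "pulse", class_roles = "event",
#'                       kernel_count = 4, kernel_size = 4, tcn_stacks = 1)
#' net <- build_network(cfg, seed = 1)
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vocseg_config"))
  if (length(config$separable_stacks) && config$channels == 1L && !config$use_stft) {
    # allowed (degenerates to a full conv) but pointless; keep silent
  }
  set.seed(seed)
  frontend <- if (config$use_stft) new_frontend(config) else NULL
  in_width <- if (config$use_stft) config$channels * config$stft_pairs else config$channels
  n_kern <- config$kernel_count
  k_size <- config$kernel_size
  dils <- stack_dilations(config)

  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }

  blocks <- list()
  width <- in_width
  for (stack in seq_len(config$tcn_stacks)) {
    separable <- stack %in% config$separable_stacks
    for (pos in seq_along(dils)) {
      blk <- list(dilation = dils[pos], separable = separable)
      if (separable) {
        lim <- sqrt(6 / (2 * k_size))
        blk$tk <- stats::runif(k_size, -lim, lim)
        blk$P <- glorot(n_kern, width, width, n_kern)
      } else {
        fan_in <- width * k_size
        fan_out <- n_kern * k_size
        blk$W <- lapply(seq_len(k_size), function(i) glorot(n_kern, width, fan_in, fan_out))
      }
      blk$b <- numeric(n_kern)
      if (width != n_kern) blk$proj <- glorot(n_kern, width, width, n_kern)
      blocks[[length(blocks) + 1L]] <- blk
      width <- n_kern
    }
  }
  n_classes <- length(all_classes(config))
  dense_in <- if (identical(config$skip_mode %||% "sum", "concat")) {
    n_kern * length(blocks)
  } else n_kern
  dense <- list(W = glorot(n_classes, dense_in, dense_in, n_classes),
                b = numeric(n_classes))
  structure(list(config = config, frontend = frontend, blocks = blocks,
                 dense = dense),
            class = "vocseg_network")
}

#' @export
print.vocseg_network <- function(x, ...) {
  cat(sprintf("<vocseg_network> %d residual blocks (%d stacks), %s, %d classes, %d parameters\n",
              length(x$blocks), x$config$tcn_stacks,
              if (is.null(x$frontend)) "no frontend" else
                sprintf("STFT frontend (%d pairs, stride %d)",
                        ncol(x$frontend$cos_bank), x$frontend$stride),
              length(all_classes(x$config)), parameter_count(x)$total))
  invisible(x)
}

#' Trainable parameter tally
#'
#' Counts trainable parameters, itemized per component. For a separable
#' block the convolution kernel contributes `tau + N * gamma` parameters
#' (shared temporal kernel of length `tau` plus `N` channel-mixing kernels
#' over `gamma` input channels) versus `tau * gamma * N` for a full block;
#' biases and residual projections are listed separately.
#'
#' @param net a `vocseg_network`.
#' @return list with `total` and a per-component breakdown.
#' @export
parameter_count <- function(net) {
  fe <- if (is.null(net$frontend)) 0L else 2L * length(net$frontend$cos_bank)
  conv <- vapply(net$blocks, function(b) {
    if (b$separable) length(b$tk) + length(b$P) else length(b$W[[1]]) * length(b$W)
  }, numeric(1))
  bias <- vapply(net$blocks, function(b) length(b$b), numeric(1))
  proj <- vapply(net$blocks, function(b) length(b$proj %||% numeric()), numeric(1))
  dense <- length(net$dense$W) + length(net$dense$b)
  list(total = as.integer(fe + sum(conv) + sum(bias) + sum(proj) + dense),
       frontend = as.integer(fe), conv_kernels = as.integer(conv),
       biases = as.integer(bias), projections = as.integer(proj),
       dense = as.integer(dense))
}

#' Repeat-upsample downsampled confidence scores
#'
#' Restores frame-rate confidence scores to the original audio rate by
#' repeating each frame `factor` times.
#'
#' @param y numeric matrix `[frames x classes]` (or a vector).
#' @param factor integer repetition factor (>= 1).
#' @return matrix `[frames * factor x classes]`.
#' @export
upsample_repeat <- function(y, factor) {
  stopifnot(factor >= 1)
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  y[rep(seq_len(nrow(y)), each = factor), , drop = FALSE]
}

# ---- forward / backward ------------------------------------------------------

# X: [channels x B*L_samp]; returns frame-rate probabilities [classes x B*Lf]
# plus caches for the backward pass when want_cache
network_fwd <- function(net, X, L_samp, want_cache = FALSE) {
  cfg <- net$config
  fe_out <- NULL
  if (!is.null(net$frontend)) {
    fe_out <- stft_fwd_int(X, net$frontend, L_samp, want_cache = want_cache)
    H <- fe_out$feat
    Lf <- fe_out$Lf
  } else {
    H <- X
    Lf <- L_samp
  }
  n <- ncol(H)
  concat <- identical(cfg$skip_mode %||% "sum", "concat")
  skip <- if (concat) matrix(0, cfg$kernel_count * length(net$blocks), n) else
    matrix(0, cfg$kernel_count, n)
  caches <- if (want_cache) vector("list", length(net$blocks)) else NULL
  x_in <- H
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    if (blk$separable) {
      sc <- sep_conv_fwd(x_in, blk$tk, blk$P, blk$b, blk$dilation, Lf)
      pre <- sc$Y
    } else {
      pre <- conv_fwd(x_in, blk$W, blk$b, blk$dilation, Lf)
    }
    act <- relu_fwd(pre)
    nm <- norm_fwd(act, want_cache = want_cache)
    z <- nm$out
    res <- if (is.null(blk$proj)) x_in else blk$proj %*% x_in
    out <- res + z
    if (concat) {
      skip[(i - 1L) * cfg$kernel_count + seq_len(cfg$kernel_count), ] <- z
    } else {
      skip <- skip + z
    }
    if (want_cache) {
      caches[[i]] <- list(x_in = x_in, pre = pre, act = act, norm = nm,
                          Xs = if (blk$separable) sc$Xs else NULL)
    }
    x_in <- out
  }
  logits <- net$dense$W %*% skip + net$dense$b
  list(logits = logits, skip = skip, Lf = Lf,
       fe_out = fe_out, caches = caches)
}

# dZ: gradient w.r.t. logits [classes x n]; returns grads mirroring net
network_bwd <- function(net, fwd, dZ) {
  cfg <- net$config
  Lf <- fwd$Lf
  g_dense <- list(W = tcrossprod(dZ, fwd$skip), b = rowSums(dZ))
  dskip <- crossprod(net$dense$W, dZ)
  n_blocks <- length(net$blocks)
  concat <- identical(cfg$skip_mode %||% "sum", "concat")
  nk <- cfg$kernel_count
  g_blocks <- vector("list", n_blocks)
  d_out <- matrix(0, nk, ncol(dZ))              # grad w.r.t. block output o
  for (i in rev(seq_len(n_blocks))) {
    blk <- net$blocks[[i]]
    cc <- fwd$caches[[i]]
    dskip_i <- if (concat) {
      dskip[(i - 1L) * nk + seq_len(nk), , drop = FALSE]
    } else dskip
    dz <- d_out + dskip_i
    d_act <- norm_bwd(dz, cc$act, cc$norm)
    d_pre <- relu_bwd(d_act, cc$pre)
    if (blk$separable) {
      cb <- sep_conv_bwd(d_pre, cc$x_in, cc$Xs, blk$tk, blk$P, blk$dilation, Lf)
      g_blocks[[i]] <- list(tk = cb$dtk, P = cb$dP, b = cb$db)
    } else {
      cb <- conv_bwd(d_pre, cc$x_in, blk$W, blk$dilation, Lf)
      g_blocks[[i]] <- list(W = cb$dW, b = cb$db)
    }
    d_in <- cb$dX
    if (is.null(blk$proj)) {
      d_in <- d_in + d_out
    } else {
      g_blocks[[i]]$proj <- tcrossprod(d_out, cc$x_in)
      d_in <- d_in + crossprod(blk$proj, d_out)
    }
    d_out <- d_in
  }
  g_frontend <- NULL
  if (!is.null(net$frontend)) {
    fb <- stft_bwd_int(d_out, net$frontend, fwd$fe_out)
    g_frontend <- list(cos_bank = fb$dcos, sin_bank = fb$dsin)
  }
  list(frontend = g_frontend, blocks = g_blocks, dense = g_dense)
}

# flatten trainable arrays in a fixed order (net and grad share structure)
collect_params <- function(net) {
  out <- list()
  if (!is.null(net$frontend)) {
    out$fe.cos <- net$frontend$cos_bank
    out$fe.sin <- net$frontend$sin_bank
  }
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    pre <- sprintf("b%03d.", i)
    if (isTRUE(blk$separable)) {
      out[[paste0(pre, "tk")]] <- blk$tk
      out[[paste0(pre, "P")]] <- blk$P
    } else {
      for (k in seq_along(blk$W)) out[[sprintf("%sW%02d", pre, k)]] <- blk$W[[k]]
    }
    out[[paste0(pre, "b")]] <- blk$b
    if (!is.null(blk$proj)) out[[paste0(pre, "proj")]] <- blk$proj
  }
  out$dense.W <- net$dense$W
  out$dense.b <- net$dense$b
  out
}

collect_grads <- function(net, grads) {
  out <- list()
  if (!is.null(net$frontend)) {
    out$fe.cos <- grads$frontend$cos_bank
    out$fe.sin <- grads$frontend$sin_bank
  }
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    g <- grads$blocks[[i]]
    pre <- sprintf("b%03d.", i)
    if (isTRUE(blk$separable)) {
      out[[paste0(pre, "tk")]] <- g$tk
      out[[paste0(pre, "P")]] <- g$P
    } else {
      for (k in seq_along(blk$W)) out[[sprintf("%sW%02d", pre, k)]] <- g$W[[k]]
    }
    out[[paste0(pre, "b")]] <- g$b
    if (!is.null(blk$proj)) out[[paste0(pre, "proj")]] <- g$proj
  }
  out$dense.W <- grads$dense$W
  out$dense.b <- grads$dense$b
  out
}

assign_params <- function(net, flat) {
  if (!is.null(net$frontend)) {
    net$frontend$cos_bank <- flat$fe.cos
    net$frontend$sin_bank <- flat$fe.sin
  }
  for (i in seq_along(net$blocks)) {
    pre <- sprintf("b%03d.", i)
    if (isTRUE(net$blocks[[i]]$separable)) {
      net$blocks[[i]]$tk <- flat[[paste0(pre, "tk")]]
      net$blocks[[i]]$P <- flat[[paste0(pre, "P")]]
    } else {
      for (k in seq_along(net$blocks[[i]]$W)) {
        net$blocks[[i]]$W[[k]] <- flat[[sprintf("%sW%02d", pre, k)]]
      }
    }
    net$blocks[[i]]$b <- flat[[paste0(pre, "b")]]
    if (!is.null(net$blocks[[i]]$proj)) {
      net$blocks[[i]]$proj <- flat[[paste0(pre, "proj")]]
    }
  }
  net$dense$W <- flat$dense.W
  net$dense$b <- flat$dense.b
  net
}

#' Save and load model checkpoints
#'
#' A checkpoint is a directory with the serialized weights (`weights.rds`)
#' and the structural configuration (`config.yaml`). Loading reconstructs a
#' network with an identical forward function.
#'
#' @param net a `vocseg_network`.
#' @param dir checkpoint directory (created if missing).
#' @export
save_checkpoint <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(net$config, file.path(dir, "config.yaml"))
  saveRDS(collect_params(net), file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- read_config(file.path(dir, "config.yaml"))$config
  net <- build_network(cfg, seed = 1L)
  assign_params(net, readRDS(file.path(dir, "weights.rds")))
}
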