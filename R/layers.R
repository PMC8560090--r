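# Low-level numerical layers: dilated and separable convolutions, rectifier,
# max-abs normalization, trainable STFT frontend, dense/softmax head.
# All feature tensors are matrices [channels x time] whose columns may hold
# B concatenated chunks of L frames each; convolutions zero-pad "same"
# (centered) and never mix frames across chunk boundaries.

# column index pairs for a temporal shift by `o` frames within chunks of
# length L: target positions receive source positions target+o
shift_cols <- function(n_cols, L, o) {
  lo <- max(1L, 1L - o)
  hi <- min(L, L - o)
  if (lo > hi) return(list(tgt = integer(), src = integer()))
  if (n_cols == L) {  # single chunk: compact ranges hit R's fast subset path
    return(list(tgt = lo:hi, src = (lo + o):(hi + o)))
  }
  base <- seq.int(lo, hi)
  offs <- seq.int(0L, n_cols - L, by = L)
  tgt <- as.vector(outer(base, offs, `+`))
  list(tgt = tgt, src = tgt + o)
}

conv_offsets <- function(kernel_size, dilation) {
  span <- (kernel_size - 1L) * dilation
  (seq_len(kernel_size) - 1L) * dilation - span %/% 2L
}

# y(t) = sum_tau W[[tau]] %*% x(t + offset_tau), zero outside the chunk
conv_fwd <- function(X, W, b, dilation, L) {
  n <- ncol(X)
  offs <- conv_offsets(length(W), dilation)
  Y <- matrix(0, nrow(W[[1]]), n)
  for (k in seq_along(W)) {
    sh <- shift_cols(n, L, offs[k])
    if (!length(sh$tgt)) next
    G <- W[[k]] %*% X
    Y[, sh$tgt] <- Y[, sh$tgt] + G[, sh$src, drop = FALSE]
  }
  Y + b
}

conv_bwd <- function(dY, X, W, dilation, L) {
  n <- ncol(X)
  offs <- conv_offsets(length(W), dilation)
  dX <- matrix(0, nrow(X), n)
  dW <- vector("list", length(W))
  for (k in seq_along(W)) {
    sh <- shift_cols(n, L, offs[k])
    if (!length(sh$tgt)) {
      dW[[k]] <- matrix(0, nrow(W[[1]]), nrow(X))
      next
    }
    dW[[k]] <- tcrossprod(dY[, sh$tgt, drop = FALSE], X[, sh$src, drop = FALSE])
    G <- crossprod(W[[k]], dY)
    dX[, sh$src] <- dX[, sh$src] + G[, sh$tgt, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

# time-channel separable convolution: one temporal kernel shared across all
# input channels, then a pointwise channel-mixing map (tau + N*gamma kernel
# parameters instead of tau*gamma*N)
sep_conv_fwd <- function(X, tk, P, b, dilation, L) {
  n <- ncol(X)
  offs <- conv_offsets(length(tk), dilation)
  Xs <- matrix(0, nrow(X), n)
  for (k in seq_along(tk)) {
    sh <- shift_cols(n, L, offs[k])
    if (!length(sh$tgt)) next
    Xs[, sh$tgt] <- Xs[, sh$tgt] + tk[k] * X[, sh$src, drop = FALSE]
  }
  list(Y = P %*% Xs + b, Xs = Xs)
}

sep_conv_bwd <- function(dY, X, Xs, tk, P, dilation, L) {
  n <- ncol(X)
  offs <- conv_offsets(length(tk), dilation)
  dXs <- crossprod(P, dY)
  dP <- tcrossprod(dY, Xs)
  dtk <- numeric(length(tk))
  dX <- matrix(0, nrow(X), n)
  for (k in seq_along(tk)) {
    sh <- shift_cols(n, L, offs[k])
    if (!length(sh$tgt)) next
    dtk[k] <- sum(dXs[, sh$tgt, drop = FALSE] * X[, sh$src, drop = FALSE])
    dX[, sh$src] <- dX[, sh$src] + tk[k] * dXs[, sh$tgt, drop = FALSE]
  }
  list(dX = dX, dtk = dtk, dP = dP, db = rowSums(dY))
}

# max-abs normalization y / (max(|y|) + 1e-5); the maximum is taken over the
# kernel (channel) axis at each time step, keeping the operation local in
# time so chunked and whole-signal inference agree exactly
NORM_EPS <- 1e-5

colmax_abs <- function(A) {
  m <- A[1, ]
  nr <- nrow(A)
  if (nr > 1L) for (i in 2:nr) m <- pmax(m, A[i, ])
  m
}

norm_fwd <- function(Y, want_cache = FALSE) {
  A <- abs(Y)
  m <- colmax_abs(A)
  inv <- 1 / (m + NORM_EPS)
  out <- Y * rep(inv, each = nrow(Y))
  if (!want_cache) return(list(out = out))
  imax <- max.col(t(A), ties.method = "first")
  list(out = out, inv = inv, imax = imax)
}

norm_bwd <- function(G, Y, cache) {
  nr <- nrow(Y)
  invr <- rep(cache$inv, each = nr)
  dY <- G * invr
  s <- colSums(G * Y)
  idx <- cbind(cache$imax, seq_len(ncol(Y)))
  dY[idx] <- dY[idx] - sign(Y[idx]) * s * cache$inv^2
  dY
}

relu_fwd <- function(X) (X > 0) * X
relu_bwd <- function(dY, X) dY * (X > 0)

# ---- trainable STFT frontend ------------------------------------------------

#' DFT-initialized STFT kernels
#'
#' Builds the initial kernels of the trainable STFT frontend: for each of the
#' first `pairs` non-negative DFT bins of window length `T`, the cos kernel
#' is `cos(2*pi*f*tau/T)` and the sin kernel is `-sin(2*pi*f*tau/T)` for
#' `tau = 0..T-1` (the real and imaginary parts of the DFT basis). Both
#' banks are trained together with the rest of the network.
#'
#' @param T_win window length in samples (>= 2).
#' @param pairs number of filter pairs (`<= T/2 + 1`).
#' @param rate optional sampling rate; when given, bin frequencies are
#'   returned in Hz, otherwise as DFT bin indices.
#' @return list with `cos_bank` and `sin_bank` (`[T x pairs]` matrices) and
#'   `frequencies`.
#' @export
init_stft_kernels <- function(T_win, pairs, rate = NULL) {
  if (T_win < 2) stop("STFT window length must be >= 2")
  if (pairs > T_win %/% 2 + 1) stop("pairs must be <= T/2 + 1")
  tau <- 0:(T_win - 1L)
  bins <- 0:(pairs - 1L)
  ang <- 2 * pi * outer(tau, bins) / T_win
  list(cos_bank = cos(ang), sin_bank = -sin(ang),
       frequencies = if (is.null(rate)) bins else bins * rate / T_win)
}

STFT_FLOOR <- 1e-10

new_frontend <- function(config) {
  k <- init_stft_kernels(config$stft_duration, config$stft_pairs, rate = config$rate)
  list(cos_bank = k$cos_bank, sin_bank = k$sin_bank,
       frequencies = k$frequencies,
       T_win = config$stft_duration, stride = config$stft_stride,
       floor = STFT_FLOOR, magnitude = "amplitude")
}

# frame one chunk of one channel into a [T x L/s] matrix, zero-padded at the
# chunk tail so that frame i covers samples i*s .. i*s+T-1
frame_chunk <- function(x, T_win, stride) {
  L <- length(x)
  starts <- seq.int(1L, L, by = stride)
  idx <- outer(0:(T_win - 1L), starts, `+`)
  xp <- c(x, numeric(T_win))
  matrix(xp[idx], nrow = T_win)
}

#' Forward pass of the (trainable) STFT frontend
#'
#' Projects strided audio frames onto the frontend's cos and sin kernel
#' banks and returns the log10 magnitude, `log10(max(sqrt(re^2 + im^2),
#' floor))`, per frame and filter. The stride downsamples the input by a
#' factor `s`; the output has `length(x) / s` frames. With multi-channel
#' input the per-channel feature blocks are stacked along the feature axis.
#'
#' @param x numeric vector or `[time x channels]` matrix; length must be a
#'   multiple of the stride (it is zero-padded up to one otherwise).
#' @param frontend a frontend parameter list (see [build_network()]); by
#'   default DFT-initialized kernels.
#' @return feature matrix `[frames x (pairs * channels)]`.
#' @export
stft_forward <- function(x, frontend) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  s <- frontend$stride
  pad <- (s - nrow(x) %% s) %% s
  if (pad > 0) x <- rbind(x, matrix(0, pad, ncol(x)))
  out <- stft_fwd_int(t(x), frontend, L_samp = nrow(x), want_cache = FALSE)
  t(out$feat)
}

# internal: X [channels x B*L_samp] -> features [channels*pairs x B*L_samp/s]
stft_fwd_int <- function(X, fe, L_samp, want_cache = FALSE) {
  n <- ncol(X)
  stopifnot(n %% L_samp == 0L, L_samp %% fe$stride == 0L)
  B <- n %/% L_samp
  Lf <- L_samp %/% fe$stride
  n_ch <- nrow(X)
  pairs <- ncol(fe$cos_bank)
  feat <- matrix(0, n_ch * pairs, B * Lf)
  cache <- if (want_cache) vector("list", B * n_ch) else NULL
  for (b in seq_len(B)) {
    for (g in seq_len(n_ch)) {
      Fm <- frame_chunk(X[g, ((b - 1L) * L_samp + 1L):(b * L_samp)], fe$T_win, fe$stride)
      re <- crossprod(fe$cos_bank, Fm)
      im <- crossprod(fe$sin_bank, Fm)
      mag <- sqrt(re^2 + im^2)
      val <- if (identical(fe$magnitude, "power")) {
        log10(pmax(mag^2, fe$floor))
      } else {
        log10(pmax(mag, fe$floor))
      }
      rows <- (g - 1L) * pairs + seq_len(pairs)
      cols <- (b - 1L) * Lf + seq_len(Lf)
      feat[rows, cols] <- val
      if (want_cache) cache[[(b - 1L) * n_ch + g]] <-
        list(Fm = Fm, re = re, im = im, mag = mag, rows = rows, cols = cols)
    }
  }
  list(feat = feat, cache = cache, Lf = Lf, B = B)
}

stft_bwd_int <- function(dFeat, fe, fwd) {
  dcos <- matrix(0, nrow(fe$cos_bank), ncol(fe$cos_bank))
  dsin <- dcos
  pow_fac <- if (identical(fe$magnitude, "power")) 2 else 1
  for (cc in fwd$cache) {
    dval <- dFeat[cc$rows, cc$cols, drop = FALSE]
    active_mag <- if (pow_fac == 2) sqrt(fe$floor) else fe$floor
    act <- cc$mag > active_mag
    dmag <- matrix(0, nrow(dval), ncol(dval))
    dmag[act] <- pow_fac * dval[act] / (cc$mag[act] * log(10))
    safe <- pmax(cc$mag, .Machine$double.xmin)
    dre <- dmag * cc$re / safe
    dim_ <- dmag * cc$im / safe
    dcos <- dcos + cc$Fm %*% t(dre)
    dsin <- dsin + cc$Fm %*% t(dim_)
  }
  list(dcos = dcos, dsin = dsin)
}

# ---- dense softmax head -----------------------------------------------------

softmax_cols <- function(Z) {
  Z <- Z - rep(colmax(Z), each = nrow(Z))
  E <- exp(Z)
  E * rep(1 / colSums(E), each = nrow(Z))
}

colmax <- function(Z) {
  m <- Z[1, ]
  if (nrow(Z) > 1L) for (i in 2:nrow(Z)) m <- pmax(m, Z[i, ])
  m
}

# categorical cross-entropy of softmax(logits) against targets; returns loss
# and gradient w.r.t. logits (mean over frames); optional class weights
softmax_xent <- function(logits, targets, class_weights = NULL) {
  P <- softmax_cols(logits)
  n <- ncol(logits)
  W <- if (is.null(class_weights)) 1 else class_weights
  lp <- log(pmax(P, 1e-12))
  loss <- -sum(W * targets * lp) / n
  wt <- if (is.null(class_weights)) {
    rep(1, n)
  } else {
    colSums(targets * class_weights)
  }
  dZ <- (P * rep(wt, each = nrow(P)) - W * targets) / n
  dimnames(dZ) <- NULL
  list(loss = loss, dZ = dZ, P = P)
}
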