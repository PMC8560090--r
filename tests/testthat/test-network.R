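ns <- asNamespace("vocseg")

test_that("STFT kernels initialize as DFT filters", {
  k <- init_stft_kernels(64, 33)
  expect_equal(dim(k$cos_bank), c(64, 33))
  expect_equal(k$cos_bank[, 1], rep(1, 64))       # f = 0: cos kernel all ones
  expect_equal(k$sin_bank[, 1], rep(0, 64))       # f = 0: sin kernel all zeros
  k4 <- init_stft_kernels(4, 3)
  expect_equal(k4$cos_bank[, 2], c(1, 0, -1, 0), tolerance = 1e-12)
  expect_equal(k4$sin_bank[, 2], c(0, -1, 0, 1), tolerance = 1e-12)
  expect_equal(init_stft_kernels(64, 33, rate = 300000)$frequencies[2], 300000 / 64)
  expect_error(init_stft_kernels(1, 1), ">= 2")
  expect_error(init_stft_kernels(8, 6), "T/2")
})

test_that("the frontend downsamples by the stride and floors the log", {
  cfg <- network_config(300000, 8192, 1, "usv", "segment", use_stft = TRUE,
                        stft_pairs = 33, stft_duration = 64, stft_stride = 16,
                        kernel_count = 4, kernel_size = 4, tcn_stacks = 1)
  fe <- ns$new_frontend(cfg)
  feat <- stft_forward(numeric(8192), fe)
  expect_equal(dim(feat), c(512, 33))              # 8192 samples -> 512 frames
  expect_true(all(feat == log10(fe$floor)))        # zero input: floored

  # a pure sinusoid at a filter's initial frequency maximizes that filter
  rate <- 32000
  cfg2 <- network_config(rate, 4096, 1, "a", "segment", use_stft = TRUE,
                         kernel_count = 4, kernel_size = 4, tcn_stacks = 1)
  fe2 <- ns$new_frontend(cfg2)
  for (bin in c(3, 10, 25)) {
    x <- sin(2 * pi * fe2$frequencies[bin + 1] * (0:4095) / rate)
    feat2 <- stft_forward(x, fe2)
    expect_equal(which.max(colMeans(feat2)), bin + 1)
  }
})

test_that("dilated convolution matches a direct-summation oracle", {
  set.seed(5)
  for (a in c(1L, 2L, 4L)) {
    X <- matrix(rnorm(3 * 40), 3)
    W <- lapply(1:4, function(i) matrix(rnorm(2 * 3), 2))
    b <- rnorm(2)
    expect_equal(ns$conv_fwd(X, W, b, a, 40L), naive_dilated_conv(X, W, b, a),
                 tolerance = 1e-12)
  }
  # an impulse through a single-channel identity kernel reproduces the
  # dilation pattern
  X <- matrix(0, 1, 21); X[1, 11] <- 1
  W <- lapply(1:3, function(i) matrix(i, 1, 1))
  out <- ns$conv_fwd(X, W, 0, 4L, 21L)
  expect_equal(which(out != 0), c(7L, 11L, 15L))
  expect_equal(out[out != 0], c(3, 2, 1))  # k(tau) applied at t - a*tau
})

test_that("normalization rescales by the max-abs and stays local", {
  Y <- rbind(c(4, -0.2), c(-2, 0.1))
  out <- ns$norm_fwd(Y)$out
  expect_equal(out[1, 1], 4 / (4 + 1e-5))
  expect_equal(out[2, 2], 0.1 / (0.2 + 1e-5))
  # all-zero input with zero bias gives zero output and skip
  cfg <- tiny_config()
  net <- build_network(cfg, seed = 1)
  fwd <- ns$network_fwd(net, matrix(0, 1, 64), 64L, want_cache = TRUE)
  expect_true(all(abs(fwd$caches[[1]]$norm$out) == 0))
  expect_true(all(fwd$skip == 0))
})

test_that("separable convolutions share the temporal kernel and count tau + N*gamma", {
  set.seed(9)
  X <- matrix(rnorm(3 * 30), 3)
  tk <- rnorm(4)
  P <- diag(3)  # one-hot channel kernels: output j = filtered input j
  out <- ns$sep_conv_fwd(X, tk, P, numeric(3), 1L, 30L)$Y
  ref <- ns$conv_fwd(X, lapply(tk, function(v) diag(v, 3)), numeric(3), 1L, 30L)
  expect_equal(out, ref, tolerance = 1e-12)

  # single channel: separable equals the full convolution exactly
  X1 <- matrix(rnorm(30), 1)
  P1 <- matrix(2.5, 1, 1)
  out1 <- ns$sep_conv_fwd(X1, tk, P1, 0, 2L, 30L)$Y
  ref1 <- ns$conv_fwd(X1, lapply(tk * 2.5, function(v) matrix(v, 1, 1)), 0, 2L, 30L)
  expect_equal(out1, ref1, tolerance = 1e-12)

  # parameter-count identity on a built model: tau + N*gamma per separable block
  cfg <- network_config(10000, 2048, 9, "pulse", "event", kernel_count = 32,
                        kernel_size = 32, tcn_stacks = 2, separable_stacks = 1)
  pc <- parameter_count(build_network(cfg, 1))
  expect_equal(pc$conv_kernels[1], 32 + 32 * 9)    # first block: gamma = 9
  expect_equal(pc$conv_kernels[2], 32 + 32 * 32)
  expect_equal(pc$conv_kernels[6], 32 * 32 * 32)   # full block in stack 2
})

test_that("built networks have the documented structure", {
  fly <- load_preset("fly_single")$config
  net <- build_network(fly, seed = 1)
  expect_length(net$blocks, 15)                       # 3 stacks x 5 blocks
  expect_equal(sapply(net$blocks, `[[`, "dilation")[1:5], c(1, 2, 4, 8, 16))
  expect_equal(net$blocks[[15]]$dilation, 16)
  expect_null(net$frontend)

  # softmax rows sum to one and output length equals input length
  x <- matrix(stats::rnorm(5000, sd = 0.3), ncol = 1)
  tr <- predict_confidence(net, recording(x, fly$rate))
  expect_equal(nrow(tr$values), 5000)
  expect_lt(max(abs(rowSums(tr$values) - 1)), 1e-6)
  expect_true(all(tr$values >= 0 & tr$values <= 1))
})

test_that("output length equals input length for every preset", {
  set.seed(2)
  for (nm in preset_names()) {
    cfg <- load_preset(nm)$config
    net <- build_network(cfg, seed = 1)
    n <- cfg$chunk_samples
    X <- matrix(stats::rnorm(cfg$channels * n, sd = 0.2), cfg$channels, n)
    fwd <- ns$network_fwd(net, X, n)
    p <- ns$softmax_cols(fwd$logits)
    stride <- if (cfg$use_stft) cfg$stft_stride else 1L
    up <- upsample_repeat(t(p), stride)
    expect_equal(nrow(up), n)
    expect_equal(ncol(up), length(all_classes(cfg)))
    expect_lt(max(abs(rowSums(up) - 1)), 1e-6)
  }
})

test_that("repeat upsampling repeats frames", {
  expect_equal(upsample_repeat(c(0.2, 0.8), 2)[, 1], c(0.2, 0.2, 0.8, 0.8))
  expect_equal(upsample_repeat(matrix(1:6, 3), 1), matrix(1:6, 3))
  expect_equal(nrow(upsample_repeat(matrix(0, 512, 2), 16)), 8192)
})

test_that("receptive field follows 1 + sum (k-1)*a through the stride", {
  cfg <- tiny_config(kernel_size = 2, residual_per_stack = 5, tcn_stacks = 1)
  expect_equal(receptive_field(cfg), 32)            # 1 + 31
  cfg1 <- tiny_config(kernel_size = 1, residual_per_stack = 5, tcn_stacks = 3)
  expect_equal(receptive_field(cfg1), 1)            # kernel 1 contributes 0
  cfg2 <- tiny_config(kernel_size = 2, residual_per_stack = 5, tcn_stacks = 2)
  expect_equal(receptive_field(cfg2) - 1, 2 * (receptive_field(cfg) - 1))
  cfg3 <- tiny_config(kernel_size = 2, residual_per_stack = 5, tcn_stacks = 1,
                      use_stft = TRUE)  # stride 4 in tiny_config
  expect_equal(receptive_field(cfg3), 32 * 4)
})

test_that("frontend at initialization matches an FFT log-magnitude oracle", {
  rate <- 32000
  set.seed(4)
  x <- 0.3 * sin(2 * pi * 2500 * (0:(rate / 2)) / rate) + rnorm(rate / 2 + 1, sd = 0.05)
  x <- x[1:16000]
  cfg <- network_config(rate, 16000 - 16000 %% 16, 1, "a", "segment",
                        use_stft = TRUE, kernel_count = 4, kernel_size = 4,
                        tcn_stacks = 1)
  fe <- ns$new_frontend(cfg)
  feat <- stft_forward(x, fe)
  xp <- c(x, numeric(64))
  for (i in seq(1, nrow(feat), by = 37)) {
    seg <- xp[((i - 1) * 16 + 1):((i - 1) * 16 + 64)]
    oracle <- log10(pmax(Mod(stats::fft(seg)[1:33]), 1e-10))
    keep <- oracle > -9  # outside the floor regime
    expect_lt(max(abs(feat[i, keep] - oracle[keep])), 1e-4)
  }
})

test_that("interior outputs are covariant to shifts by one stride", {
  cfg <- tiny_config(use_stft = TRUE, chunk_samples = 256)
  net <- build_network(cfg, seed = 3)
  set.seed(8)
  x <- rnorm(512, sd = 0.4)
  s <- cfg$stft_stride
  f1 <- ns$network_fwd(net, matrix(x, 1), 512L)
  f2 <- ns$network_fwd(net, matrix(c(numeric(s), x[1:(512 - s)]), 1), 512L)
  p1 <- ns$softmax_cols(f1$logits)
  p2 <- ns$softmax_cols(f2$logits)
  interior <- 16:(512 / s - 16)  # away from both edges
  expect_equal(p2[, interior + 1L], p1[, interior], tolerance = 1e-10)
})

test_that("checkpoints reconstruct an identical forward function", {
  cfg <- tiny_config(use_stft = TRUE)
  net <- build_network(cfg, seed = 6)
  dir <- tempfile()
  save_checkpoint(net, dir)
  net2 <- load_checkpoint(dir)
  x <- matrix(stats::rnorm(256, sd = 0.3), 1)
  expect_equal(ns$network_fwd(net2, x, 256L)$logits,
               ns$network_fwd(net, x, 256L)$logits, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  for (skip_mode in c("sum", "concat")) {
    cfg <- network_config(1000, 64, 2, c("a", "b"), c("event", "segment"),
                          use_stft = FALSE, kernel_count = 5, kernel_size = 3,
                          tcn_stacks = 2, residual_per_stack = 2,
                          separable_stacks = 2, skip_mode = skip_mode)
    net <- build_network(cfg, seed = 3)
    set.seed(42)
    X <- matrix(rnorm(2 * 128, sd = 0.5), 2, 128)
    k <- length(all_classes(cfg))
    Tm <- matrix(runif(k * 128), k, 128)
    Tm <- Tm / rep(colSums(Tm), each = k)
    loss_of <- function(n) {
      fwd <- ns$network_fwd(n, X, 64L)
      ns$softmax_xent(fwd$logits, Tm)$loss
    }
    fwd <- ns$network_fwd(net, X, 64L, want_cache = TRUE)
    sx <- ns$softmax_xent(fwd$logits, Tm)
    g <- ns$collect_grads(net, ns$network_bwd(net, fwd, sx$dZ))
    flat <- ns$collect_params(net)
    eps <- 1e-6
    for (nm in names(flat)) {
      i <- sample(length(flat[[nm]]), 1)
      f2 <- flat; f2[[nm]][i] <- flat[[nm]][i] + eps
      lp <- loss_of(ns$assign_params(net, f2))
      f2[[nm]][i] <- flat[[nm]][i] - eps
      lm <- loss_of(ns$assign_params(net, f2))
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i])),
                1e-4)
    }
  }
})

test_that("concatenated skip combination yields valid confidences", {
  cfg <- tiny_config(skip_mode = "concat")
  net <- build_network(cfg, seed = 4)
  expect_equal(nrow(net$dense$W), 3)
  expect_equal(ncol(net$dense$W), cfg$kernel_count * 3)  # 3 residual blocks
  fwd <- ns$network_fwd(net, matrix(rnorm(256, sd = 0.3), 1), 256L)
  p <- ns$softmax_cols(fwd$logits)
  expect_lt(max(abs(colSums(p) - 1)), 1e-9)
})
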