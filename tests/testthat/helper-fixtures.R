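# shared fixtures, built in code at test time

# a deliberately tiny network configuration for fast unit tests
tiny_config <- function(rate = 1000, channels = 1, use_stft = FALSE,
                        classes = c(pulse = "event", sine = "segment"),
                        kernel_count = 6, kernel_size = 4, tcn_stacks = 1,
                        residual_per_stack = 3, chunk_samples = 256, ...) {
  network_config(rate = rate, chunk_samples = chunk_samples, channels = channels,
                 class_names = names(classes), class_roles = unname(classes),
                 use_stft = use_stft, stft_pairs = 5, stft_duration = 8,
                 stft_stride = 4, kernel_count = kernel_count,
                 kernel_size = kernel_size, tcn_stacks = tcn_stacks,
                 residual_per_stack = residual_per_stack, ...)
}

# naive O(n^2) direct-summation dilated convolution oracle:
# y_i(t) = sum_{tau, gamma} k_i(tau, gamma) x(t - a*tau + span/2, gamma)
# (centered same padding, matching the layer's convention)
naive_dilated_conv <- function(X, W, b, dilation) {
  K <- length(W)
  n <- ncol(X)
  span <- (K - 1L) * dilation
  loff <- span %/% 2L
  Y <- matrix(0, nrow(W[[1]]), n)
  for (t in seq_len(n)) {
    acc <- b
    for (tau in seq_len(K)) {
      src <- t + (tau - 1L) * dilation - loff
      if (src >= 1 && src <= n) acc <- acc + W[[tau]] %*% X[, src]
    }
    Y[, t] <- acc
  }
  Y
}

# brute-force maximum bipartite matching of predictions to true events
# within tolerance (optimum number of matches), for instances <= ~12 events
brute_force_matches <- function(true_times, pred_times, tol) {
  nt <- length(true_times); np <- length(pred_times)
  if (!nt || !np) return(0L)
  best <- 0L
  rec <- function(i, used_t, count) {
    if (count + (np - i + 1L) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    rec(i + 1L, used_t, count)  # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!used_t[j] && abs(pred_times[i] - true_times[j]) <= tol) {
        used_t[j] <- TRUE
        rec(i + 1L, used_t, count + 1L)
        used_t[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nt), 0L)
  best
}

# plain recursive Levenshtein distance (the textbook definition)
recursive_levenshtein <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  min(recursive_levenshtein(a[-1], b) + 1L,
      recursive_levenshtein(a, b[-1]) + 1L,
      recursive_levenshtein(a[-1], b[-1]) + (a[1] != b[1]))
}

# three spectro-temporally distinct bird-like syllable templates
three_templates <- function() {
  list(
    syllable_template("up", 80, cbind(c(0, 1), c(2000, 5000)), harmonics = 1),
    syllable_template("down", 60, cbind(c(0, 1), c(6000, 2500)), harmonics = 1),
    syllable_template("flat2h", 100, cbind(c(0, 0.5, 1), c(3500, 3500, 3500)),
                      harmonics = c(1, 0.6))
  )
}
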