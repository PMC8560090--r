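test_that("event matching applies the nearest-kept dedup rule", {
  m <- match_events(c(0.100, 0.200), c(0.103, 0.400), tolerance = 0.010)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 1, 1))
  expect_equal(m$matched_pairs$true, 0.100)

  # two predictions near one true event: the closer one wins
  m2 <- match_events(0.100, c(0.095, 0.104), tolerance = 0.010)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1, 1, 0))
  expect_equal(m2$matched_pairs$predicted, 0.104)

  m3 <- match_events(c(0.1, 0.2, 0.3), numeric(), 0.010)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 0, 3))

  # displaced prediction is re-matched to the remaining true event
  m4 <- match_events(c(0.100, 0.105), c(0.101, 0.099), 0.010)
  expect_equal(c(m4$TP, m4$FP, m4$FN), c(2, 0, 0))
})

test_that("count identities hold on random instances", {
  set.seed(41)
  for (rep in 1:100) {
    tr <- sort(runif(sample(0:8, 1)))
    pr <- sort(runif(sample(0:8, 1)))
    m <- match_events(tr, pr, 0.05)
    expect_equal(m$TP + m$FN, length(tr))
    expect_equal(m$TP + m$FP, length(pr))
    if (nrow(m$matched_pairs)) {
      expect_lte(max(abs(m$matched_pairs$true - m$matched_pairs$predicted)), 0.05)
    }
  }
})

test_that("greedy matching attains the bipartite optimum for separated events", {
  set.seed(43)
  tol <- 0.01
  for (rep in 1:50) {
    nt <- sample(1:8, 1)
    tr <- cumsum(runif(nt, 2.5 * tol, 10 * tol))  # separation > 2x tolerance
    pr <- unlist(lapply(tr, function(t) if (runif(1) < 0.8) t + runif(1, -tol, tol)))
    pr <- sort(c(pr, runif(sample(0:3, 1), 0, max(tr))))
    m <- match_events(tr, pr, tol)
    expect_equal(m$TP, brute_force_matches(tr, pr, tol))
  }
})

test_that("pseudo true negatives follow the windows-minus-events formula", {
  expect_equal(pseudo_true_negatives(1, 0.010, 10), 40)   # 50 windows - 10
  expect_equal(pseudo_true_negatives(1, 0.010, 60), 0)    # clipped
  expect_equal(pseudo_true_negatives(1, 0.5, 0), 1)
})

test_that("metrics follow the P/R/F1/accuracy formulas", {
  counts <- match_events(seq(0.1, 1, by = 0.1), c(seq(0.1, 0.8, by = 0.1), 2, 3),
                         0.01)
  m <- event_metrics(counts)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)

  perfect <- event_metrics(match_events(c(0.1, 0.2), c(0.1, 0.2), 0.01))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  # random counts against direct formula evaluation
  set.seed(47)
  for (rep in 1:20) {
    cts <- structure(list(TP = sample(0:20, 1), FP = sample(0:20, 1),
                          FN = sample(0:20, 1), TN = NA_real_,
                          matched_pairs = data.frame(true = numeric(),
                                                     predicted = numeric())),
                     class = "vocseg_counts")
    m <- suppressWarnings(event_metrics(cts, tn = 50))
    P <- if (cts$TP + cts$FP == 0) 0 else cts$TP / (cts$TP + cts$FP)
    R <- if (cts$TP + cts$FN == 0) 0 else cts$TP / (cts$TP + cts$FN)
    expect_equal(m$precision, P)
    expect_equal(m$recall, R)
    expect_equal(m$f1, if (P + R == 0) 0 else 2 * P * R / (P + R))
    expect_equal(m$accuracy, (cts$TP + 50) / (cts$TP + 50 + cts$FP + cts$FN))
  }
  empty <- structure(list(TP = 0, FP = 0, FN = 0, TN = NA_real_,
                          matched_pairs = data.frame(true = numeric(),
                                                     predicted = numeric())),
                     class = "vocseg_counts")
  expect_warning(expect_warning(event_metrics(empty), "undefined"))
})

test_that("temporal error is the median absolute matched distance", {
  pairs <- data.frame(true = c(0.1, 0.2, 0.3),
                      predicted = c(0.099, 0.2, 0.303))
  expect_equal(temporal_error(pairs), 0.001)
  expect_equal(temporal_error(data.frame(true = 0.5, predicted = 0.5)), 0)
  set.seed(53)
  off <- rnorm(31, sd = 0.002)
  pairs2 <- data.frame(true = seq_len(31), predicted = seq_len(31) + off)
  expect_equal(temporal_error(pairs2), sort(abs(off))[16])
})

test_that("metrics are robust to the tolerance when errors are far smaller", {
  set.seed(59)
  tr <- cumsum(runif(40, 0.08, 0.2))
  pr <- tr + runif(40, -5e-4, 5e-4)
  f1s <- sapply(c(0.005, 0.01, 0.02, 0.04), function(tol) {
    event_metrics(match_events(tr, pr, tol))$f1
  })
  expect_true(all(f1s == f1s[1]))
})

test_that("segment confusion counts samples and syllables correctly", {
  tl <- c(rep("a", 40), rep("no_song", 20), rep("b", 40))
  same <- segment_confusion(tl, tl)
  expect_equal(sum(diag(same$confusion)), 100)
  expect_equal(same$accuracy, 1)

  allno <- segment_confusion(tl, rep("no_song", 100))
  expect_equal(allno$per_class[["a"]]$recall, 0)
  expect_equal(allno$per_class[["b"]]$recall, 0)
  expect_equal(sum(allno$confusion[, "no_song"]), 100)

  # sample-mode equals a pairwise counting oracle
  set.seed(61)
  t2 <- sample(c("a", "b", "no_song"), 200, replace = TRUE)
  p2 <- sample(c("a", "b", "no_song"), 200, replace = TRUE)
  cm <- segment_confusion(t2, p2)$confusion
  for (x in c("a", "b", "no_song")) for (y in c("a", "b", "no_song")) {
    expect_equal(unname(cm[x, y]), sum(t2 == x & p2 == y))
  }

  seg <- data.frame(onset = c(0.00, 0.06), offset = c(0.04, 0.10))
  syl <- segment_confusion(c(rep("a", 50), rep("b", 50)),
                           c(rep("a", 30), rep("b", 70)),
                           mode = "syllable", segments = seg, rate = 1000)
  expect_equal(sum(syl$confusion), 2)
  expect_equal(unname(syl$confusion["a", "a"]), 1)
  expect_equal(unname(syl$confusion["b", "b"]), 1)

  expect_error(segment_confusion(c("a", "b"), "a"), "equal length")
})

test_that("sequence error rate is the normalized edit distance", {
  expect_equal(sequence_error_rate(c("A", "B", "C"), c("A", "B", "C")), 0)
  expect_equal(sequence_error_rate(c("A", "B", "C"), c("A", "B", "D")), 1 / 3)
  expect_equal(sequence_error_rate(c("A", "B", "C"), character()), 1)
  expect_error(sequence_error_rate(character(), "A"), "non-empty")

  # against the independent C implementation in utils::adist
  set.seed(67)
  for (rep in 1:50) {
    a <- sample(c("x", "y", "z"), sample(1:8, 1), replace = TRUE)
    b <- sample(c("x", "y", "z"), sample(0:8, 1), replace = TRUE)
    expect_equal(sequence_error_rate(a, b) * length(a),
                 as.numeric(utils::adist(paste(a, collapse = ""),
                                         paste(b, collapse = ""))))
  }

  # triangle inequality of the underlying distance
  set.seed(71)
  for (rep in 1:20) {
    s <- lapply(1:3, function(i) sample(c("x", "y"), sample(1:6, 1), replace = TRUE))
    d <- function(u, v) sequence_error_rate(u, v) * length(u)
    expect_lte(d(s[[1]], s[[3]]), d(s[[1]], s[[2]]) + d(s[[2]], s[[3]]))
  }
})

test_that("pulse SNR separates center energy from margin noise", {
  rate <- 10000
  pt <- make_pulse_train(pulse_train_params(train_length = 4, amplitude = 0.8),
                         rate, seed = 3)
  comp <- list(list(waveform = pt$waveform, at = 0.5,
                    annotations = events_to_annotations(pt$event_times, "pulse")))
  clean <- make_recording(comp, 2, rate, seed = 1)
  ev <- clean$annotations$start_seconds
  s0 <- snr_pulse(clean$recording, ev)
  expect_true(all(s0$snr > 50))  # margins are silent

  # stationary white noise only: SNR ~ 1
  noise_rec <- make_recording(list(), 2, rate,
                              noise = noise_params(gaussian_rms = 0.1), seed = 2)
  s1 <- snr_pulse(noise_rec$recording, c(0.5, 1.0, 1.5))
  expect_lt(max(abs(s1$snr - 1)), 0.4)  # sampling error of 50/100-sample RMS

  # doubling the amplitude doubles the SNR (given identical noise)
  noisy1 <- make_recording(comp, 2, rate,
                           noise = noise_params(gaussian_rms = 0.05), seed = 7)
  comp2 <- comp; comp2[[1]]$waveform <- 2 * comp[[1]]$waveform
  noisy2 <- make_recording(comp2, 2, rate,
                           noise = noise_params(gaussian_rms = 0.05), seed = 7)
  r1 <- snr_pulse(noisy1$recording, ev)$snr
  r2 <- snr_pulse(noisy2$recording, ev)$snr
  expect_equal(r2 / r1, rep(2, length(ev)), tolerance = 0.15)

  # edge events are skipped with a warning
  expect_warning(snr_pulse(clean$recording, 0.001), "skipped")
  # global gain invariance
  gained <- clean$recording; gained$samples <- gained$samples * 7
  expect_equal(snr_pulse(gained, ev)$snr, s0$snr)
})

test_that("sine SNR uses 200 ms flanks with a 10 ms buffer", {
  rate <- 10000
  n <- 3 * rate
  set.seed(5)
  x <- rnorm(n, sd = 0.05)
  tseg <- seq(0, 0.5 - 1 / rate, by = 1 / rate)
  a_amp <- 0.4
  x[5001:10000] <- x[5001:10000] + a_amp * sin(2 * pi * 150 * tseg)
  rec <- recording(x, rate)
  seg <- data.frame(onset = 0.5, offset = 1.0)
  s <- snr_sine(rec, seg)
  expect_equal(s$snr, (a_amp / sqrt(2)) / 0.05, tolerance = 0.12)

  # a segment ending at 1.0 s must not use samples before 1.010 s as noise:
  # make 1.010-1.210 s loud and verify the SNR responds
  x2 <- x; x2[10101:12100] <- x2[10101:12100] * 10
  s2 <- snr_sine(recording(x2, rate), seg)
  expect_lt(s2$snr, s$snr / 2)

  # zero-noise flanks give Inf
  quiet <- numeric(n)
  quiet[5001:10000] <- a_amp * sin(2 * pi * 150 * tseg)
  expect_equal(snr_sine(recording(quiet, rate), seg)$snr, Inf)

  # labeled sine/pulse samples are excluded from the flanks
  ann <- annotations("sine", 1.01, 1.21)
  s3 <- snr_sine(recording(x2, rate), seg, ann = ann)
  expect_equal(s3$snr, s$snr, tolerance = 0.35)
  # gain invariance
  s4 <- snr_sine(recording(3 * x, rate), seg)
  expect_equal(s4$snr, s$snr)
})

test_that("mouse SNR follows the additive power model", {
  rate <- 300000
  set.seed(9)
  noise_sd <- 0.02
  x <- rnorm(rate / 2, sd = noise_sd)
  s0 <- snr_mouse(recording(x, rate))
  expect_lt(stats::median(s0$snr), 0.5)
  expect_true(all(s0$snr >= 0))

  # embedded tone raising the total power to 4x the noise power: by the
  # additive model the SNR inside the tone is (4 - 1)/1 = 3 (the
  # low-percentile floor underestimates sigma_noise slightly, so the
  # estimate sits a little above 3)
  tone_amp <- sqrt(6) * noise_sd         # tone power = 3 * noise power
  idx <- 60001:90000
  x2 <- x
  x2[idx] <- x2[idx] + tone_amp * sin(2 * pi * 50000 * seq_along(idx) / rate)
  s1 <- snr_mouse(recording(x2, rate))
  inside <- s1$snr[s1$time > 0.21 & s1$time < 0.29]
  expect_equal(stats::median(inside), 3, tolerance = 0.25)
  # gain invariance
  s2 <- snr_mouse(recording(10 * x2, rate))
  expect_equal(s2$snr, s1$snr, tolerance = 1e-9)
})
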