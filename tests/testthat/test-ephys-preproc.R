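test_that("band-pass keeps the spike band and rejects DC and mains hum", {
  fs <- 30000
  t <- seq(0, 1, by = 1 / fs)
  tone <- sin(2 * pi * 1000 * t)
  out <- bandpass(matrix(tone, ncol = 1), fs_hz = fs)
  i <- 3000:27000  # interior, clear of filter transients
  expect_lt(abs(max(abs(out[i, 1])) - 1), 0.01)
  dc <- bandpass(matrix(rep(3, fs), ncol = 1), fs_hz = fs)
  expect_lt(max(abs(dc[i, 1])), 1e-6)
  hum <- sin(2 * pi * 50 * t)
  hout <- bandpass(matrix(hum, ncol = 1), fs_hz = fs)
  atten_db <- 20 * log10(max(abs(hout[i, 1])))
  expect_lt(atten_db, -20)
  expect_error(bandpass(matrix(tone, ncol = 1), fs_hz = 8000), "Nyquist")
})

test_that("z-scoring standardizes channels and flags degenerate ones", {
  set.seed(8)
  x <- cbind(rnorm(4000, 3, 2), rnorm(4000, -1, 0.5))
  z <- zscore_channels(x)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-10)
  expect_equal(zscore_channels(z), z, tolerance = 1e-8)
  expect_error(zscore_channels(cbind(rnorm(100), rep(2, 100))), "2")
})

test_that("diagonal-weighted whitening blends between z-scoring and whitening", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  # alpha = 1: full whitening, output covariance identity
  w1 <- modified_whitening(S, 1)
  expect_equal(w1$W_new %*% S %*% t(w1$W_new), diag(2), tolerance = 1e-12)
  # alpha = 0 on diagonal covariance: pure per-channel standardization
  w0 <- modified_whitening(diag(c(4, 9)), 0)
  expect_equal(w0$W_new, diag(c(1 / 2, 1 / 3)), tolerance = 1e-12)
  # alpha = 0.1: elementwise blend against an eigendecomposition oracle
  eig <- eigen(S, symmetric = TRUE)
  W_oracle <- eig$vectors %*% diag(1 / sqrt(eig$values)) %*% t(eig$vectors)
  w <- modified_whitening(S, 0.1)
  expect_equal(w$W_new, 0.1 * W_oracle + 0.9 * diag(diag(W_oracle)),
               tolerance = 1e-12)
  expect_error(modified_whitening(matrix(c(1, 2, 2, 1), 2), 0.1),
               "positive-definite")
  expect_error(modified_whitening(matrix(c(1, 2, 3, 4), 2), 0.1), "symmetric")
})

test_that("mean-waveform extraction averages snippets and handles edges", {
  fs <- 30000
  n <- fs  # 1 s
  snippet_t <- ((0:119) - 60) / fs
  x <- matrix(0, n, 2)
  spikes <- c(0.2, 0.4, 0.6)
  for (s in spikes) {
    k <- round(s * fs) + 1
    x[k + (-60:59), 1] <- x[k + (-60:59), 1] + spike_template(snippet_t)
    x[k + (-60:59), 2] <- x[k + (-60:59), 2] + 0.5 * spike_template(snippet_t)
  }
  wf <- extract_mean_waveforms(x, spikes, fs_hz = fs)
  expect_equal(dim(wf$waveforms), c(120, 2))
  expect_equal(wf$waveforms[, 1], spike_template(snippet_t), tolerance = 1e-12)
  # single spike: the mean is that snippet
  wf1 <- extract_mean_waveforms(x, spikes[1], fs_hz = fs)
  expect_equal(wf1$waveforms[, 2], 0.5 * spike_template(snippet_t),
               tolerance = 1e-12)
  # spike at t = 0 is dropped with a warning
  expect_warning(w2 <- extract_mean_waveforms(x, c(0, spikes), fs_hz = fs),
                 "dropped 1")
  expect_equal(w2$n_spikes_used, 3)
  expect_error(extract_mean_waveforms(x, 0, fs_hz = fs), "no usable spikes")
})

test_that("averaging k noisy repeats shrinks residual noise like 1/sqrt(k)", {
  fs <- 30000
  set.seed(14)
  template <- spike_template(((0:119) - 60) / fs)
  noise_of <- function(k) {
    x <- matrix(rnorm(fs * 2), ncol = 1)
    spikes <- seq(0.1, 1.8, length.out = k)
    for (s in spikes) {
      ki <- round(s * fs) + 1
      x[ki + (-60:59), 1] <- x[ki + (-60:59), 1] + 5 * template
    }
    wf <- extract_mean_waveforms(x, spikes, fs_hz = fs)
    sd(wf$waveforms[, 1] - 5 * template)
  }
  r4 <- mean(vapply(1:6, function(i) noise_of(4), numeric(1)))
  r64 <- mean(vapply(1:6, function(i) noise_of(64), numeric(1)))
  expect_lt(abs(r4 / r64 - 4) / 4, 0.2)  # sqrt(64/4) = 4
})

test_that("round-robin correction recovers the frame-time signal", {
  fs <- 30000; adc <- 1.05e6; n <- 240
  k <- 0:(n - 1)
  for (slot in c(0, 17, 34)) {
    skewed <- sin(2 * pi * 2000 * (k / fs + slot / adc))
    ref <- sin(2 * pi * 2000 * k / fs)
    out <- correct_round_robin(matrix(skewed, ncol = 1),
                               acquisition_order = slot, adc_hz = adc,
                               fs_hz = fs)
    i <- 40:(n - 40)
    rms <- sqrt(mean((out[i, 1] - ref[i])^2)) / sqrt(mean(ref[i]^2))
    if (slot == 0) expect_equal(out[, 1], skewed)  # slot 0: unchanged
    else expect_lt(rms, 0.01)
  }
  # per-channel frame rate identity of the multiplexer
  cfg <- recording_config()
  expect_identical(cfg$adc_hz / cfg$n_slots, cfg$fs_hz)
  expect_error(correct_round_robin(matrix(0, 10, 2),
                                   acquisition_order = c(1, 1),
                                   fs_hz = fs), "duplicate")
})
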