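test_that("cross-correlation equals a brute-force double loop", {
  set.seed(20)
  for (i in 1:8) {
    n <- sample(16:256, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- cross_correlation(x, y)
    oracle <- xcorr_oracle(x, y)
    expect_equal(ours$lags, oracle$lags)
    expect_equal(ours$c, oracle$c, tolerance = 1e-12)
  }
})

test_that("pair lags recover integer, fractional, and zero shifts", {
  fs <- 30000
  x <- spike_template(((0:119) - 60) / fs)
  # identical waveforms: zero lag within the sub-sample refinement tolerance
  expect_lt(abs(pair_lag(x, x, fs)$dt_s * fs), 0.25)
  # integer shift of 3 samples, against the brute-force oracle's argmax
  x3 <- c(rep(0, 3), x[1:117])
  pl <- pair_lag(x, x3, fs)
  oracle <- xcorr_oracle(x, x3)
  expect_equal(oracle$lags[which.max(oracle$c)], -3)
  expect_equal(pl$dt_s * fs, 3, tolerance = 0.05)
  # band-limited 2.5-sample shift: sub-sample refinement within 0.25 samples
  x25 <- spike_template(((0:119) - 60 - 2.5) / fs)
  pl25 <- pair_lag(x, x25, fs)
  expect_lt(abs(pl25$dt_s * fs - 2.5), 0.25)
  expect_true(pl25$refined)
  expect_error(pair_lag(rep(0, 50), rnorm(50), fs), "all-zero")
})

test_that("pair lags are antisymmetric", {
  fs <- 30000
  set.seed(23)
  base <- spike_template(((0:119) - 60) / fs)
  for (shift in c(1, 2.5, 7, -4)) {
    y <- spike_template(((0:119) - 60 - shift) / fs)
    dij <- pair_lag(base, y, fs)$dt_s
    dji <- pair_lag(y, base, fs)$dt_s
    expect_equal(dij, -dji, tolerance = 0.1 / fs)
  }
})

test_that("velocity recovery is within 5% across the physiological range", {
  vs <- c(0.33, 0.5, 1, 2, 5)
  errs <- vapply(seq_along(vs), function(i) {
    est <- recover_velocity(vs[i], n_spikes = 50, amplitude = 5, noise_sd = 1,
                            seed = 100 + i)
    (est$v_mps - vs[i]) / vs[i]
  }, numeric(1))
  expect_true(all(abs(errs) < 0.05))
  # no systematic sign trend in the bias across the grid
  expect_true(any(errs > 0) && any(errs < 0) ||
                mean(abs(errs)) < 0.01)
})

test_that("reversed propagation flips the sign but not the magnitude", {
  up <- recover_velocity(2, seed = 7)
  down <- recover_velocity(-2, seed = 7)
  expect_identical(up$direction, "ascending")
  expect_identical(down$direction, "descending")
  expect_gt(up$v_mps, 0)
  expect_lt(down$v_mps, 0)
  expect_lt(abs(abs(down$v_mps) - abs(up$v_mps)) / abs(up$v_mps), 0.05)
})

test_that("eligibility and exclusion rules are enforced", {
  probe <- make_probe(4, 4, 150)
  cfg <- recording_config(duration_s = 1.5, noise_sd = 1, seed = 31)
  rec <- simulate_recording(probe, unit_spec(2, 0.1, n_spikes = 30), cfg)
  proc <- zscore_channels(bandpass(rec))
  wf <- correct_round_robin(extract_mean_waveforms(proc, rec$spike_times[[1]]))
  # an amplitude-0.1 unit leaves every channel below 1.5 SD
  expect_error(estimate_velocity(wf, probe), "eligible")
  # within-shank pairs (dx = 0) never enter the ledger
  est <- recover_velocity(2, seed = 3)
  expect_true(all(est$pairs$dx_um != 0))
  # ledger mean identity
  expect_equal(est$v_mps, mean(est$pairs$v_pair_mps[est$pairs$used]))
})

test_that("observational bounds match the geometry arithmetic", {
  probe <- make_probe(4, 4, 150)
  b <- observational_bounds(probe, fs_hz = 30000, window_ms = 4)
  expect_equal(b$v_max_mps, 13.5)
  expect_equal(b$v_min_mps, 0.225)
  expect_equal(b$v_min_printed_mps, 0.23)
  b2 <- observational_bounds(probe, fs_hz = 60000, window_ms = 4)
  expect_equal(b2$v_max_mps, 27)
  expect_equal(b2$v_min_mps, 0.225)
  expect_error(observational_bounds(make_probe(1, 4, 150)), "zero")
})

test_that("out-of-bounds estimates are flagged, never silent", {
  probe <- make_probe(4, 4, 150)
  # near-simultaneous arrivals at 12 m/s-like lags cannot happen at 30 m/s;
  # fake a waveform set with a tiny lag to force |V| > v_max
  fs <- 30000
  wf <- matrix(0, 120, 16)
  base_t <- ((0:119) - 60) / fs
  pos <- probe$channel_map$x_um
  for (ch in 1:16) wf[, ch] <- 5 * spike_template(base_t - pos[ch] * 1e-6 / 30)
  wfs <- structure(list(waveforms = wf, fs_hz = fs, window_ms = 4,
                        n_spikes_used = 1, channel_positions_um = pos,
                        acquisition_order = probe$acquisition_order,
                        n_slots = probe$n_slots, adc_hz = 1.05e6,
                        time_corrected = TRUE),
                   class = "mean_waveform_set")
  est <- estimate_velocity(wfs, probe)
  expect_gt(abs(est$v_mps), 13.5)
  expect_true(est$flagged)
})

test_that("latency conversion covers the reference arithmetic", {
  expect_equal(to_latency(10, 0.01), 1)
  expect_equal(to_latency(2, 220e-6), 0.11)
  expect_equal(to_latency(0.044, 220e-6), 5)
  expect_equal(to_latency(-2, 0.01), to_latency(2, 0.01))  # magnitude only
  expect_error(to_latency(0), "zero velocity")
})

test_that("direction comparison delegates to KS and Shapiro-Wilk", {
  a <- c(1.2, 2.1, 2.4, 3.3, 1.8)
  r <- compare_directions(a, a)
  expect_equal(r$ks_p, 1)
  expect_error(compare_directions(a, a[1:2]), "at least 3")
  # same-distribution draws: rejection rate near alpha
  set.seed(40)
  p_same <- vapply(1:200, function(i)
    compare_directions(rnorm(100, 2), rnorm(100, 2))$ks_p, numeric(1))
  expect_lt(mean(p_same < 0.05), 0.10)
  # a 1-SD shift at n = 100 is detected nearly always
  p_shift <- vapply(1:50, function(i)
    compare_directions(rnorm(100, 3), rnorm(100, 4))$ks_p, numeric(1))
  expect_gt(mean(p_shift < 0.05), 0.9)
})
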