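# Independent oracles used across the suite.

# brute-force cross-correlation: double loop, no vectorized sum
xcorr_oracle <- function(x_i, x_j, max_lag = length(x_i) %/% 2) {
  n <- length(x_i)
  lags <- -max_lag:max_lag
  cc <- numeric(length(lags))
  for (li in seq_along(lags)) {
    s <- 0
    for (t in seq_len(n)) {
      st <- t + lags[li]
      if (st >= 1 && st <= n) s <- s + x_i[st] * x_j[t]
    }
    cc[li] <- s
  }
  list(lags = lags, c = cc)
}

# shoelace area from an explicit coordinate loop
shoelace_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# vertices of a circle as a polygon trace
circle_coords <- function(r, n = 720, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# one simulated unit run through the full velocity pipeline
recover_velocity <- function(v_true, n_spikes = 50, amplitude = 5,
                             noise_sd = 1, seed = 1, probe = make_probe()) {
  cfg <- recording_config(duration_s = max(1.5, n_spikes / 30),
                          noise_sd = noise_sd, seed = seed)
  rec <- simulate_recording(probe, unit_spec(v_true, amplitude,
                                             n_spikes = n_spikes), cfg)
  proc <- zscore_channels(bandpass(rec))
  wf <- extract_mean_waveforms(proc, rec$spike_times[[1]])
  wf <- correct_round_robin(wf)
  estimate_velocity(wf, probe)
}
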