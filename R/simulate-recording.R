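#' Biphasic extracellular spike template
#'
#' Difference-of-Gaussians waveform used as the generic extracellular spike
#' shape of the recording simulator: a negative-going main lobe of about
#' 1.2 ms total width followed by a smaller positive rebound, normalized to
#' unit peak absolute amplitude. Evaluated as a continuous function of time
#' so the simulator can sample it at each channel's true (multiplexer-
#' skewed) acquisition times.
#'
#' @param t_s Time relative to the spike center, seconds (vectorized).
#' @param main_sigma_s SD of the main Gaussian lobe, seconds. The main lobe
#'   spans roughly `6 * main_sigma_s` (default 0.2 ms giving a 1.2 ms lobe).
#' @param rebound_frac Amplitude of the positive rebound relative to the
#'   main lobe.
#' @param rebound_delay_s Center of the rebound lobe, seconds after the main
#'   lobe.
#' @param rebound_sigma_s SD of the rebound lobe, seconds.
#' @return Numeric vector of template values; peak absolute value 1, main
#'   lobe negative (extracellular convention).
#' @export
spike_template <- function(t_s, main_sigma_s = 2e-4, rebound_frac = 0.45,
                           rebound_delay_s = 5e-4, rebound_sigma_s = 3e-4) {
  w <- -exp(-t_s^2 / (2 * main_sigma_s^2)) +
    rebound_frac * exp(-(t_s - rebound_delay_s)^2 / (2 * rebound_sigma_s^2))
  w
}

#' Define a simulated unit
#'
#' @param velocity_mps Signed conduction velocity, m/s. Positive velocity
#'   means propagation toward increasing axial coordinate ("ascending" under
#'   this package's sign convention). `Inf` (or `-Inf`) marks a unit whose
#'   spikes arrive simultaneously on all channels. Zero is invalid.
#' @param amplitude_sd Peak spike amplitude in units of the noise SD.
#' @param rate_hz Mean firing rate (homogeneous Poisson), used when
#'   `n_spikes` is `NULL`.
#' @param n_spikes Optional exact spike count; spike times are then drawn
#'   uniformly over the valid interior of the recording.
#' @param template Function of time (seconds, centered on the spike)
#'   returning waveform values; default [spike_template()].
#' @return A list of class `unit_spec`.
#' @export
unit_spec <- function(velocity_mps, amplitude_sd = 5, rate_hz = 20,
                      n_spikes = NULL, template = spike_template) {
  if (!is.na(velocity_mps) && velocity_mps == 0)
    stop("velocity of 0 is undefined for a propagating unit")
  if (amplitude_sd <= 0) stop("amplitude_sd must be positive")
  structure(list(velocity_mps = velocity_mps, amplitude_sd = amplitude_sd,
                 rate_hz = rate_hz, n_spikes = n_spikes, template = template),
            class = "unit_spec")
}

#' Recording configuration
#'
#' Nominal per-channel rate, ADC multiplexer rate and slot count of the
#' acquisition system. The multiplexer samples all channel slots
#' sequentially within one frame, so `adc_hz / n_slots` must equal `fs_hz`
#' exactly (1.05 MHz / 35 slots = 30 kHz for the defaults).
#'
#' @param fs_hz Per-channel sampling rate, Hz.
#' @param adc_hz Multiplexer (aggregate ADC) rate, Hz.
#' @param n_slots Slots per multiplexer frame.
#' @param duration_s Recording length, seconds.
#' @param noise_sd Additive Gaussian noise SD per sample.
#' @param seed Optional RNG seed for the simulation.
#' @return A list of class `recording_config`.
#' @export
recording_config <- function(fs_hz = 30000, adc_hz = 1.05e6, n_slots = 35,
                             duration_s = 1, noise_sd = 1, seed = NULL) {
  if (abs(adc_hz / n_slots - fs_hz) > 1e-9 * fs_hz)
    stop("adc_hz / n_slots must equal fs_hz")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(fs_hz = fs_hz, adc_hz = adc_hz, n_slots = as.integer(n_slots),
                 duration_s = duration_s, noise_sd = noise_sd, seed = seed),
            class = "recording_config")
}

#' Simulate a multi-shank extracellular recording
#'
#' Generates a raw recording of spiking units propagating along a probe.
#' A spike of a unit with velocity `v` that crosses the probe origin (the
#' most proximal recording site) at time `t0` arrives at a channel with
#' axial position `x` at `t0 + (x - x0) / v`. Each channel's samples are
#' taken at its true acquisition times `k / fs + slot / adc_hz`, where
#' `slot` is the channel's position in the ADC round-robin, emulating the
#' sub-sample timing skew of a multiplexed headstage. Independent Gaussian
#' noise of SD `noise_sd` is added to every sample.
#'
#' @param geometry A [make_probe()] object.
#' @param units List of [unit_spec()] objects (a single `unit_spec` is
#'   accepted).
#' @param config A [recording_config()].
#' @return A list of class `raw_recording` with elements `data` (numeric
#'   matrix, samples x channels, amplitudes in noise-SD units),
#'   `spike_times` (list per unit of true spike times in seconds, on the
#'   frame clock), `geometry`, `config`, and `sign_convention`
#'   (`"positive velocity = ascending (toward increasing axial coordinate)"`).
#' @examples
#' probe <- make_probe(4, 4, 150)
#' cfg <- recording_config(duration_s = 0.5, seed = 1)
#' rec <- simulate_recording(probe, unit_spec(2, n_spikes = 20), cfg)
#' dim(rec$data)
#' @export
simulate_recording <- function(geometry, units, config = recording_config()) {
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(config, "recording_config"))
  if (inherits(units, "unit_spec")) units <- list(units)
  for (u in units) {
    if (!inherits(u, "unit_spec")) stop("units must be unit_spec objects")
    if (u$velocity_mps == 0) stop("velocity of 0 gives undefined propagation")
  }

  fs <- config$fs_hz
  n_samples <- floor(config$duration_s * fs)
  n_channels <- nrow(geometry$channel_map)
  x_um <- geometry$channel_map$x_um
  x0 <- min(x_um)
  slot_offset_s <- geometry$acquisition_order / config$adc_hz
  template_half_s <- 2e-3  # templates vanish outside a 4 ms support
  edge_s <- 2 * template_half_s

  with_seed(config$seed, {
    data <- matrix(rnorm(n_samples * n_channels, sd = config$noise_sd),
                   nrow = n_samples, ncol = n_channels)
    spike_times <- vector("list", length(units))
    for (ui in seq_along(units)) {
      u <- units[[ui]]
      n_spk <- if (!is.null(u$n_spikes)) u$n_spikes
               else rpois(1, u$rate_hz * config$duration_s)
      t_spk <- sort(runif(n_spk, edge_s, config$duration_s - edge_s))
      spike_times[[ui]] <- t_spk
      delay_s <- if (is.finite(u$velocity_mps))
        (x_um - x0) * 1e-6 / u$velocity_mps else rep(0, n_channels)
      for (t0 in t_spk) {
        for (ch in seq_len(n_channels)) {
          arrive <- t0 + delay_s[ch]
          k0 <- floor((arrive - template_half_s - slot_offset_s[ch]) * fs)
          k1 <- ceiling((arrive + template_half_s - slot_offset_s[ch]) * fs)
          k <- max(k0, 0):min(k1, n_samples - 1)
          t_sample <- k / fs + slot_offset_s[ch]
          data[k + 1, ch] <- data[k + 1, ch] +
            u$amplitude_sd * u$template(t_sample - arrive)
        }
      }
    }
    structure(list(data = data, spike_times = spike_times,
                   geometry = geometry, config = config,
                   sign_convention = paste("positive velocity = ascending",
                                           "(toward increasing axial coordinate)")),
              class = "raw_recording")
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d samples x %d channels at %g kHz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$config$fs_hz / 1000,
              nrow(x$data) / x$config$fs_hz))
  cat(sprintf("  %d unit(s); %s\n", length(x$spike_times), x$sign_convention))
  invisible(x)
}
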