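#' Zero-phase band-pass filter a multichannel recording
#'
#' 4th-order Butterworth band-pass (default 300-5000 Hz, the spike band)
#' applied forward-backward (`signal::filtfilt`) per channel, so the filter
#' is zero-phase and does not bias spike arrival times. DC is removed by
#' construction.
#'
#' @param recording Numeric matrix, samples x channels, or a
#'   `raw_recording` (filtered in place, returned as the same class).
#' @param fs_hz Sampling rate; taken from the recording object when given.
#' @param lo,hi Band edges, Hz. `hi` must be below the Nyquist rate.
#' @param order Butterworth order (per pass).
#' @return Filtered object of the same organization.
#' @export
bandpass <- function(recording, fs_hz = NULL, lo = 300, hi = 5000, order = 4) {
  is_rec <- inherits(recording, "raw_recording")
  x <- if (is_rec) recording$data else as.matrix(recording)
  if (is_rec && is.null(fs_hz)) fs_hz <- recording$config$fs_hz
  if (is.null(fs_hz)) stop("fs_hz required")
  if (hi >= fs_hz / 2) stop("upper band edge must be below the Nyquist rate")
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi")
  bf <- signal::butter(order, c(lo, hi) / (fs_hz / 2), type = "pass")
  out <- apply(x, 2, function(ch) signal::filtfilt(bf, ch))
  if (is_rec) {
    recording$data <- out
    recording
  } else out
}

#' Z-score each channel of a recording
#'
#' Standardizes every channel to mean 0 and SD 1 over the whole recording,
#' so all downstream amplitudes (and the eligibility threshold of
#' [estimate_velocity()]) are in units of that channel's standard
#' deviation.
#'
#' @param recording Samples x channels matrix or `raw_recording`.
#' @return Same organization, standardized.
#' @export
zscore_channels <- function(recording) {
  is_rec <- inherits(recording, "raw_recording")
  x <- if (is_rec) recording$data else as.matrix(recording)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ", paste(which(sds == 0), collapse = ", "))
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  if (is_rec) {
    recording$data <- out
    recording
  } else out
}

#' Diagonal-weighted whitening matrix
#'
#' Computes the blend
#' \deqn{W_{new} = \alpha W + (1 - \alpha) W_{diag}}
#' between the full symmetric whitening matrix \eqn{W = \Sigma^{-1/2}}
#' (inverse symmetric square root of the channel covariance) and its
#' diagonal-only form \eqn{W_{diag}}. At `alpha = 0` the transform purely
#' z-scores channels; at `alpha = 1` it is ordinary whitening. Recordings
#' of parallel axon tracts have very high cross-channel correlations —
#' spikes appear on many channels at once — so full whitening removes real
#' signal; a small `alpha` (0.1) keeps channels near-independent scaling
#' while lightly decorrelating noise.
#'
#' @param covariance Symmetric positive-definite channel covariance.
#' @param alpha Blend weight in [0, 1].
#' @return List of class `whitening_spec`: `W_new`, `W`, `W_diag`, `alpha`.
#' @export
modified_whitening <- function(covariance, alpha = 0.1) {
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-8))
    stop("covariance must be symmetric")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  eig <- eigen(covariance, symmetric = TRUE)
  if (any(eig$values <= 0))
    stop("covariance is not positive-definite")
  W <- eig$vectors %*% diag(1 / sqrt(eig$values), nrow(covariance)) %*%
    t(eig$vectors)
  W_diag <- diag(diag(W), nrow(covariance))
  structure(list(W_new = alpha * W + (1 - alpha) * W_diag,
                 W = W, W_diag = W_diag, alpha = alpha),
            class = "whitening_spec")
}

#' Extract mean spike waveforms per channel
#'
#' Cuts a window (default 4 ms) around every spike on every channel and
#' averages the aligned snippets, producing one mean waveform per channel.
#' Spikes too close to the record edges for a full window are dropped with
#' a warning giving the count.
#'
#' @param recording Samples x channels matrix (already band-passed and
#'   z-scored) or `raw_recording`.
#' @param spike_times_s Spike times in seconds (frame clock).
#' @param fs_hz Sampling rate; taken from a `raw_recording` when given.
#' @param window_ms Window length, ms.
#' @param geometry Optional `probe_geometry` carrying channel positions
#'   and acquisition order (taken from a `raw_recording` automatically).
#' @return Object of class `mean_waveform_set`: `waveforms` (window
#'   samples x channels), `fs_hz`, `window_ms`, `n_spikes_used`,
#'   `channel_positions_um`, `acquisition_order`, `n_slots`, `adc_hz`,
#'   `time_corrected` (FALSE until [correct_round_robin()]).
#' @export
extract_mean_waveforms <- function(recording, spike_times_s, fs_hz = NULL,
                                   window_ms = 4, geometry = NULL) {
  is_rec <- inherits(recording, "raw_recording")
  x <- if (is_rec) recording$data else as.matrix(recording)
  if (is_rec) {
    if (is.null(fs_hz)) fs_hz <- recording$config$fs_hz
    if (is.null(geometry)) geometry <- recording$geometry
  }
  if (is.null(fs_hz)) stop("fs_hz required")
  n_win <- round(fs_hz * window_ms / 1000)
  offsets <- -(n_win %/% 2):(n_win - n_win %/% 2 - 1)
  centers <- round(spike_times_s * fs_hz) + 1  # 1-based sample index
  ok <- centers + min(offsets) >= 1 & centers + max(offsets) <= nrow(x)
  if (sum(ok) == 0) stop("no usable spikes: all within half a window of an edge")
  if (any(!ok))
    warning(sprintf("dropped %d spike(s) within half a window of a record edge",
                    sum(!ok)))
  centers <- centers[ok]
  wf <- matrix(0, length(offsets), ncol(x))
  for (s in centers) wf <- wf + x[s + offsets, , drop = FALSE]
  wf <- wf / length(centers)
  structure(list(waveforms = wf, fs_hz = fs_hz, window_ms = window_ms,
                 n_spikes_used = length(centers),
                 channel_positions_um = if (!is.null(geometry))
                   geometry$channel_map$x_um else NULL,
                 acquisition_order = if (!is.null(geometry))
                   geometry$acquisition_order else NULL,
                 n_slots = if (!is.null(geometry)) geometry$n_slots else NULL,
                 adc_hz = if (is_rec) recording$config$adc_hz else NULL,
                 time_corrected = FALSE),
            class = "mean_waveform_set")
}

# windowed-sinc fractional-delay evaluation: value of the band-limited
# signal x (samples at 0..n-1) at positions pos (in samples)
sinc_interp <- function(x, pos, half_width = 32) {
  n <- length(x)
  vapply(pos, function(p) {
    k <- max(0, floor(p) - half_width):min(n - 1, ceiling(p) + half_width)
    u <- p - k
    s <- ifelse(u == 0, 1, sin(pi * u) / (pi * u))
    w <- 0.5 * (1 + cos(pi * u / (half_width + 1)))  # Hann taper
    sum(x[k + 1] * s * w)
  }, numeric(1))
}

#' Correct round-robin ADC sampling skew
#'
#' A multiplexed headstage samples its channels sequentially, so a channel
#' assigned ADC slot `s` is really acquired `s / adc_hz` seconds after the
#' nominal frame time (up to ~one frame period across 35 slots at
#' 1.05 MHz). This function resamples each channel's mean waveform from
#' its true acquisition times onto the common frame-time base, using
#' band-limited (windowed-sinc) interpolation by default or a cubic spline.
#'
#' @param wfset A `mean_waveform_set` (with `acquisition_order`), or a
#'   plain samples x channels matrix (then `acquisition_order` and
#'   `adc_hz`/`fs_hz` must be given).
#' @param acquisition_order Slot index per channel (0-based); defaults to
#'   the one stored in `wfset`.
#' @param adc_hz Multiplexer rate (default the stored value, else
#'   1.05e6).
#' @param method `"sinc"` (default) or `"cubic"`.
#' @return The same object with waveforms on the common frame-time base
#'   and `time_corrected = TRUE`.
#' @export
correct_round_robin <- function(wfset, acquisition_order = NULL,
                                adc_hz = NULL, fs_hz = NULL,
                                method = c("sinc", "cubic")) {
  method <- match.arg(method)
  is_set <- inherits(wfset, "mean_waveform_set")
  wf <- if (is_set) wfset$waveforms else as.matrix(wfset)
  if (is_set) {
    if (is.null(acquisition_order)) acquisition_order <- wfset$acquisition_order
    if (is.null(adc_hz)) adc_hz <- wfset$adc_hz
    if (is.null(fs_hz)) fs_hz <- wfset$fs_hz
  }
  if (is.null(adc_hz)) adc_hz <- 1.05e6
  if (is.null(acquisition_order)) stop("acquisition_order required")
  if (length(acquisition_order) != ncol(wf))
    stop("need one acquisition slot per channel")
  if (anyDuplicated(acquisition_order)) stop("duplicate ADC slots")
  if (is.null(fs_hz)) stop("fs_hz required")

  frac <- acquisition_order * fs_hz / adc_hz  # delay in samples, in [0, 1)
  n <- nrow(wf)
  out <- wf
  for (ch in seq_len(ncol(wf))) {
    if (frac[ch] == 0) next
    # sample m of channel ch was taken at frame time m + frac; the value at
    # frame time k is the underlying signal at sample position k - (-frac)?
    # The stored series is y[m] = s(m + frac); we want s(k) = y at position
    # k - frac on the stored grid.
    pos <- (seq_len(n) - 1) - frac[ch]
    out[, ch] <- switch(method,
      sinc = sinc_interp(wf[, ch], pos),
      cubic = spline(x = seq_len(n) - 1, y = wf[, ch], xout = pos,
                     method = "natural")$y)
  }
  if (is_set) {
    wfset$waveforms <- out
    wfset$time_corrected <- TRUE
    wfset
  } else out
}
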