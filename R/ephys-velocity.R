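#' Cross-correlation of two mean waveforms over a lag range
#'
#' Unnormalized cross-correlation
#' \deqn{c_{ij}[l] = \sum_t x_i[t + l] \cdot x_j[t]}
#' over lags `l` spanning half the window each way, with zero padding
#' outside the support. No amplitude normalization is applied: channels are
#' z-scored upstream, so correlation magnitudes are comparable as-is.
#'
#' @param x_i,x_j Equal-length numeric vectors (mean waveforms).
#' @param max_lag Maximum |lag| in samples (default `floor(n / 2)`).
#' @return List: `lags` (samples), `c` (correlation at each lag).
#' @export
cross_correlation <- function(x_i, x_j, max_lag = NULL) {
  n <- length(x_i)
  if (length(x_j) != n) stop("waveforms must have equal length")
  if (is.null(max_lag)) max_lag <- n %/% 2
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    t_idx <- seq_len(n)
    s_idx <- t_idx + l
    ok <- s_idx >= 1 & s_idx <= n
    sum(x_i[s_idx[ok]] * x_j[t_idx[ok]])
  }, numeric(1))
  list(lags = lags, c = cc)
}

#' Time lag between two channels by cross-correlation peak refinement
#'
#' Finds the lag maximizing the cross-correlation of two mean waveforms and
#' refines it to sub-sample precision by fitting a quadratic through the 4
#' largest correlation values; the vertex of the quadratic is the refined
#' lag. The fit falls back to the discrete argmax when the top-4 lags are
#' not contiguous, the quadratic is degenerate or opens upward, or its
#' vertex leaves the lag span — the refinement is only meaningful near a
#' single well-formed peak.
#'
#' Sign convention: positive `dt_s` means channel *j* lags channel *i*
#' (the signal arrives at *j* later). With axial positions, `dx / dt` is
#' then a signed velocity, positive toward increasing axial coordinate.
#'
#' @param x_i,x_j Equal-length mean waveforms.
#' @param fs_hz Sampling rate of the (common) waveform time base.
#' @param dx_um Optional site separation to carry in the result, um
#'   (`x_j` position minus `x_i` position).
#' @return List of class `lag_estimate`: `dt_s`, `lag_samples` (refined,
#'   fractional), `dx_um`, `refined` (TRUE if the quadratic was used),
#'   `lags`, `c`.
#' @export
pair_lag <- function(x_i, x_j, fs_hz, dx_um = NA_real_) {
  if (all(x_i == 0) || all(x_j == 0)) stop("all-zero waveform")
  cc <- cross_correlation(x_i, x_j)
  top <- order(cc$c, decreasing = TRUE)[seq_len(min(4, length(cc$c)))]
  refined <- FALSE
  lag_hat <- cc$lags[which.max(cc$c)]
  if (length(top) == 4 && max(top) - min(top) == 3) {
    lx <- cc$lags[top]; ly <- cc$c[top]
    fit <- lm(ly ~ lx + I(lx^2))
    a <- coef(fit)[3]; b <- coef(fit)[2]
    if (is.finite(a) && a < 0) {
      vertex <- -b / (2 * a)
      if (vertex >= min(cc$lags) && vertex <= max(cc$lags)) {
        lag_hat <- unname(vertex)
        refined <- TRUE
      }
    }
  }
  # c peaks at lag = -(arrival_j - arrival_i) in samples, so dt flips sign
  structure(list(dt_s = -lag_hat / fs_hz, lag_samples = lag_hat,
                 dx_um = dx_um, refined = refined,
                 lags = cc$lags, c = cc$c),
            class = "lag_estimate")
}

#' Estimate conduction velocity from a set of mean waveforms
#'
#' For every pair of channels whose mean-waveform peak amplitude exceeds
#' `amp_threshold_sd` (z-score units) and whose axial separation is
#' non-zero, the pairwise time lag is measured with [pair_lag()] and the
#' velocity estimated as the arithmetic mean of `dx / dt` over the eligible
#' pairs. Pairs whose |lag| is below one ADC slot period cannot be resolved
#' in time (the signal is simultaneous at the acquisition resolution);
#' they are excluded from the mean and counted as near-simultaneous in the
#' ledger. Estimates whose magnitude falls outside the observational
#' bounds of the geometry are flagged, never silently returned.
#'
#' @param wfset A `mean_waveform_set` (ideally after
#'   [correct_round_robin()]).
#' @param geometry A `probe_geometry`; defaults to positions stored in
#'   `wfset`.
#' @param amp_threshold_sd Eligibility threshold on peak |amplitude| per
#'   channel, in SD units.
#' @param window_ms Spike window used for the observational bounds
#'   (default the waveform window).
#' @return Object of class `velocity_estimate`: `v_mps`, `direction`
#'   (`"ascending"` if positive under the package convention), `pairs`
#'   (ledger data frame: `i`, `j`, `dx_um`, `dt_s`, `v_pair_mps`, `used`),
#'   `n_pairs`, `n_near_simultaneous`, `eligible_channels`,
#'   `amp_threshold_sd`, `flagged`, `bounds`.
#' @export
estimate_velocity <- function(wfset, geometry = NULL, amp_threshold_sd = 1.5,
                              window_ms = NULL) {
  stopifnot(inherits(wfset, "mean_waveform_set"))
  pos <- if (!is.null(geometry)) geometry$channel_map$x_um
         else wfset$channel_positions_um
  if (is.null(pos)) stop("channel positions unavailable")
  wf <- wfset$waveforms
  if (is.null(window_ms)) window_ms <- wfset$window_ms
  amp <- apply(abs(wf), 2, max)
  eligible <- which(amp > amp_threshold_sd)
  if (length(eligible) < 2)
    stop("no eligible channel pairs: fewer than 2 channels exceed the amplitude threshold")

  slot_period_s <- if (!is.null(wfset$adc_hz)) 1 / wfset$adc_hz else 1 / 1.05e6
  pairs <- utils::combn(eligible, 2)
  ledger <- data.frame(i = integer(0), j = integer(0), dx_um = numeric(0),
                       dt_s = numeric(0), v_pair_mps = numeric(0),
                       used = logical(0))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    dx <- pos[j] - pos[i]
    if (dx == 0) next  # within-shank pair: no axial separation
    le <- pair_lag(wf[, i], wf[, j], wfset$fs_hz, dx_um = dx)
    near <- abs(le$dt_s) < slot_period_s
    ledger <- rbind(ledger, data.frame(
      i = i, j = j, dx_um = dx, dt_s = le$dt_s,
      v_pair_mps = if (near) NA_real_ else dx * 1e-6 / le$dt_s,
      used = !near))
  }
  if (nrow(ledger) == 0)
    stop("no eligible pairs: all eligible channels share one axial position")
  if (!any(ledger$used))
    stop("unresolvable velocity: all pairs near-simultaneous at the ADC resolution")

  v <- mean(ledger$v_pair_mps[ledger$used])
  b <- tryCatch(observational_bounds(geometry %||% list(
    max_separation_um = diff(range(pos))), wfset$fs_hz, window_ms),
    error = function(e) NULL)
  flagged <- !is.null(b) && (abs(v) > b$v_max_mps || abs(v) < b$v_min_mps)
  structure(list(v_mps = v,
                 direction = if (v > 0) "ascending" else "descending",
                 pairs = ledger, n_pairs = sum(ledger$used),
                 n_near_simultaneous = sum(!ledger$used),
                 eligible_channels = eligible,
                 amp_threshold_sd = amp_threshold_sd,
                 flagged = flagged, bounds = b,
                 sign_convention = paste("positive velocity = ascending",
                                         "(toward increasing axial coordinate)")),
            class = "velocity_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("velocity estimate: %.3f m/s (%s), %d pair(s) used, %d near-simultaneous%s\n",
              x$v_mps, x$direction, x$n_pairs, x$n_near_simultaneous,
              if (x$flagged) " [FLAGGED: outside observational bounds]" else ""))
  invisible(x)
}

#' Observational velocity bounds of a probe geometry
#'
#' The fastest measurable velocity is set by the sample period over the
#' longest available baseline (`v_max = max separation / one sample
#' period`); the slowest by the largest measurable lag, half the spike
#' window (`v_min = max separation / (window / 2)`). For a 4-shank probe
#' with 150 um spacing (450 um span), 30 kHz sampling and a 4 ms window
#' these are 13.5 and 0.225 m/s. `v_min_printed_mps` rounds half-up to two
#' decimals (0.23).
#'
#' @param geometry A `probe_geometry` (or any list with
#'   `max_separation_um`).
#' @param fs_hz Per-channel sampling rate.
#' @param window_ms Spike window, ms.
#' @return List: `v_max_mps`, `v_min_mps`, `v_min_printed_mps`,
#'   `max_separation_um`.
#' @examples
#' observational_bounds(make_probe(4, 4, 150), 30000, 4)
#' @export
observational_bounds <- function(geometry, fs_hz = 30000, window_ms = 4) {
  sep_um <- geometry$max_separation_um
  if (is.null(sep_um) || sep_um <= 0)
    stop("zero maximum axial separation: bounds undefined")
  sep_m <- sep_um * 1e-6
  v_max <- sep_m * fs_hz
  v_min <- sep_m / (window_ms / 1000 / 2)
  # half-up with an epsilon guard: 0.225 * 100 is 22.499... in binary
  half_up <- function(x, digits) {
    s <- 10^digits
    floor(x * s + 0.5 + sqrt(.Machine$double.eps)) / s
  }
  list(v_max_mps = v_max, v_min_mps = v_min,
       v_min_printed_mps = half_up(v_min, 2),
       max_separation_um = sep_um)
}

#' Latency over a travel length
#'
#' Converts a conduction velocity into the traversal latency of a stated
#' path length (default 1 cm, a typical hawkmoth neck-connective length).
#'
#' @param velocity_mps Signed or unsigned velocity, m/s (vectorized,
#'   nonzero).
#' @param length_m Travel length, m.
#' @return Latency in milliseconds.
#' @examples
#' to_latency(10)          # 1 ms over 1 cm
#' to_latency(0.044, 220e-6)  # 5 ms over a fruit-fly-scale connective
#' @export
to_latency <- function(velocity_mps, length_m = 0.01) {
  if (any(velocity_mps == 0)) stop("zero velocity: latency undefined")
  (length_m / abs(velocity_mps)) * 1000
}

#' Compare ascending and descending velocity distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the velocity magnitudes of the two
#' directions, plus a Shapiro-Wilk normality test on the pooled magnitudes;
#' both delegated to the standard implementations.
#'
#' @param velocities_ascending,velocities_descending Numeric vectors of
#'   signed velocities (>= 3 each); magnitudes are compared.
#' @return List: `ks_statistic`, `ks_p`, `shapiro_w`, `shapiro_p`, `n`.
#' @export
compare_directions <- function(velocities_ascending, velocities_descending) {
  if (length(velocities_ascending) < 3 || length(velocities_descending) < 3)
    stop("need at least 3 samples per direction")
  a <- abs(velocities_ascending)
  d <- abs(velocities_descending)
  ks <- suppressWarnings(ks.test(a, d))
  sw <- shapiro.test(c(a, d))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       n = c(ascending = length(a), descending = length(d)))
}
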