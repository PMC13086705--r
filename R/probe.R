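#' Construct a multi-shank probe geometry
#'
#' Builds the geometry of a multi-shank microelectrode array inserted along
#' an axon tract, of the kind used to measure conduction velocity from the
#' arrival-time differences of a propagating spike. The default corresponds
#' to a 4-shank, 4-sites-per-shank array with 150 um between adjacent shanks
#' and all sites of a shank axially co-located (a tetrode cluster), so the
#' maximum axial separation between recording sites is 450 um.
#'
#' Channels are numbered shank-by-shank. Each channel is also assigned an
#' ADC multiplexer slot (see [simulate_recording()]): the amplifier samples
#' its channels sequentially in a round-robin at `n_slots` times the
#' per-channel rate, so a channel in slot `s` is acquired `s / adc_hz`
#' seconds after the nominal frame time. The default assignment is slot
#' `channel - 1`.
#'
#' @param n_shanks Number of shanks (>= 1).
#' @param sites_per_shank Number of recording sites on each shank.
#' @param shank_spacing_um Axial distance between adjacent shanks, um
#'   (strictly positive).
#' @param site_offsets_um Within-shank axial offsets of the sites, um.
#'   Either length 1 (recycled) or `sites_per_shank`. Default 0: sites of a
#'   shank are treated as axially co-located.
#' @param n_slots Number of ADC multiplexer slots per frame (default 35,
#'   i.e. 32 channels plus 3 utility slots at a 1.05 MHz multiplexer rate
#'   serving 30 kHz channels).
#' @param acquisition_order Integer vector, one ADC slot index in
#'   `0:(n_slots - 1)` per channel; must be unique. Default
#'   `seq_len(n_channels) - 1`.
#'
#' @return An object of class `probe_geometry`: a list with `channel_map`
#'   (data frame: `channel`, `shank`, `site`, `x_um` axial position),
#'   `n_shanks`, `sites_per_shank`, `shank_spacing_um`, `n_slots`,
#'   `acquisition_order`, and `max_separation_um`.
#'
#' @examples
#' probe <- make_probe(4, 4, 150)
#' probe$max_separation_um  # 450
#' @export
make_probe <- function(n_shanks = 4, sites_per_shank = 4, shank_spacing_um = 150,
                       site_offsets_um = 0, n_slots = 35,
                       acquisition_order = NULL) {
  if (n_shanks < 1) stop("n_shanks must be >= 1")
  if (sites_per_shank < 1) stop("sites_per_shank must be >= 1")
  if (!is.finite(shank_spacing_um) || shank_spacing_um <= 0)
    stop("invalid geometry: shank spacing must be strictly positive")
  if (length(site_offsets_um) == 1)
    site_offsets_um <- rep(site_offsets_um, sites_per_shank)
  if (length(site_offsets_um) != sites_per_shank)
    stop("site_offsets_um must have length 1 or sites_per_shank")

  n_channels <- n_shanks * sites_per_shank
  shank <- rep(seq_len(n_shanks), each = sites_per_shank)
  site <- rep(seq_len(sites_per_shank), times = n_shanks)
  x_um <- (shank - 1) * shank_spacing_um + site_offsets_um[site]
  channel_map <- data.frame(channel = seq_len(n_channels),
                            shank = shank, site = site, x_um = x_um)

  if (is.null(acquisition_order)) acquisition_order <- seq_len(n_channels) - 1L
  acquisition_order <- as.integer(acquisition_order)
  if (length(acquisition_order) != n_channels)
    stop("acquisition_order must give one slot per channel")
  if (anyDuplicated(acquisition_order))
    stop("acquisition_order slots must be unique")
  if (any(acquisition_order < 0) || any(acquisition_order >= n_slots))
    stop("acquisition_order slots must lie in 0:(n_slots - 1)")

  out <- list(channel_map = channel_map,
              n_shanks = n_shanks,
              sites_per_shank = sites_per_shank,
              shank_spacing_um = shank_spacing_um,
              site_offsets_um = site_offsets_um,
              n_slots = as.integer(n_slots),
              acquisition_order = acquisition_order,
              max_separation_um = max(x_um) - min(x_um))
  class(out) <- "probe_geometry"
  out
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("probe_geometry: %d shanks x %d sites, %g um shank spacing\n",
              x$n_shanks, x$sites_per_shank, x$shank_spacing_um))
  cat(sprintf("  %d channels, max axial separation %g um, %d ADC slots\n",
              nrow(x$channel_map), x$max_separation_um, x$n_slots))
  invisible(x)
}
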