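#' Write a recording as raw int16 plus a JSON sidecar
#'
#' Serializes a recording to the package's on-disk exchange format:
#' little-endian int16 samples in channel-major frames (all channels of
#' frame 0, then frame 1, ...) plus a JSON sidecar holding the sampling
#' rates, multiplexer layout, probe geometry and the int16 scale factor.
#'
#' @param recording A `raw_recording` or samples x channels matrix.
#' @param path Output path for the binary data; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param scale Amplitude units per int16 count (values are divided by
#'   this before rounding).
#' @param geometry,config Required when `recording` is a bare matrix.
#' @return Invisibly, the sidecar list.
#' @export
write_recording <- function(recording, path, scale = 1e-3,
                            geometry = NULL, config = NULL) {
  is_rec <- inherits(recording, "raw_recording")
  x <- if (is_rec) recording$data else as.matrix(recording)
  if (is_rec) {
    geometry <- geometry %||% recording$geometry
    config <- config %||% recording$config
  }
  if (is.null(geometry) || is.null(config))
    stop("geometry and config required to write a sidecar")
  q <- as.integer(round(t(x) / scale))  # channel-major frames
  if (any(abs(q) > 32767)) stop("int16 overflow: increase scale")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(q, con, size = 2, endian = "little")
  sidecar <- list(fs_hz = config$fs_hz, adc_hz = config$adc_hz,
                  n_slots = config$n_slots,
                  n_channels = ncol(x), n_samples = nrow(x),
                  scale = scale,
                  channel_map = geometry$channel_map,
                  acquisition_order = geometry$acquisition_order,
                  shank_spacing_um = geometry$shank_spacing_um,
                  sign_convention = if (is_rec) recording$sign_convention
                                    else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar)
}

#' Read a raw int16 recording and its JSON sidecar
#'
#' @param path Path written by [write_recording()].
#' @return A `raw_recording` (spike times empty; geometry rebuilt from the
#'   sidecar).
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- sidecar$n_samples * sidecar$n_channels
  con <- file(path, "rb")
  on.exit(close(con))
  q <- readBin(con, "integer", n = n, size = 2, endian = "little",
               signed = TRUE)
  data <- t(matrix(q, nrow = sidecar$n_channels)) * sidecar$scale
  cm <- as.data.frame(sidecar$channel_map)
  geometry <- structure(list(
    channel_map = cm,
    n_shanks = length(unique(cm$shank)),
    sites_per_shank = max(cm$site),
    shank_spacing_um = sidecar$shank_spacing_um,
    site_offsets_um = 0,
    n_slots = as.integer(sidecar$n_slots),
    acquisition_order = as.integer(sidecar$acquisition_order),
    max_separation_um = max(cm$x_um) - min(cm$x_um)),
    class = "probe_geometry")
  config <- recording_config(fs_hz = sidecar$fs_hz, adc_hz = sidecar$adc_hz,
                             n_slots = sidecar$n_slots,
                             duration_s = sidecar$n_samples / sidecar$fs_hz)
  structure(list(data = data, spike_times = list(), geometry = geometry,
                 config = config,
                 sign_convention = sidecar$sign_convention),
            class = "raw_recording")
}

#' Write a label or binary mask as an image
#'
#' Label masks go to 16-bit TIFF (up to 65535 labels); binary masks may
#' also go to PNG (stored 8-bit as 0/255).
#'
#' @param mask Integer matrix (labels for TIFF; strictly 0/1 for PNG).
#' @param path Output path; format from the extension (`.tif`/`.tiff` or
#'   `.png`).
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(mask) > 1)
      stop("PNG masks are binary; write label masks as 16-bit TIFF")
    EBImage::writeImage(EBImage::Image(t(mask != 0) * 1), path)
  } else {
    EBImage::writeImage(EBImage::Image(t(mask) / 65535), path,
                        bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a label or binary mask written by [write_mask()]
#'
#' @param path Image path.
#' @return Integer matrix (rows = depth, cols = span); labels for TIFF,
#'   0/1 for PNG.
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  m <- t(EBImage::imageData(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  else matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
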