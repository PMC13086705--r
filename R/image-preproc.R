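#' Generate a stack of tiles sharing a multiplicative brightness pattern
#'
#' Each tile is an independent random content image multiplied elementwise
#' by one shared gradient, emulating the persistent brightness gradients and
#' fixed-pattern noise of a TEM camera that flat-field correction is meant
#' to remove.
#'
#' @param n_tiles Number of tiles (>= 2).
#' @param dim Tile dimensions `c(rows, cols)`.
#' @param gradient Either a matrix of `dim`, or `NULL` for a default linear
#'   left-right ramp from 0.5 to 1.5.
#' @param content_seed Optional RNG seed for the tile contents.
#' @param content_mean,content_sd Mean and SD of the (positive, clamped)
#'   Gaussian tile contents.
#' @return List of class `tile_stack`: `tiles` (list of matrices),
#'   `gradient`, `dim`.
#' @export
generate_tile_stack <- function(n_tiles, dim = c(64, 64), gradient = NULL,
                                content_seed = NULL, content_mean = 0.5,
                                content_sd = 0.1) {
  stopifnot(n_tiles >= 2, length(dim) == 2)
  if (is.null(gradient))
    gradient <- matrix(seq(0.5, 1.5, length.out = dim[2]),
                       nrow = dim[1], ncol = dim[2], byrow = TRUE)
  stopifnot(all(dim(gradient) == dim))
  with_seed(content_seed, {
    tiles <- lapply(seq_len(n_tiles), function(i) {
      content <- matrix(pmax(rnorm(prod(dim), content_mean, content_sd), 0.01),
                        dim[1], dim[2])
      content * gradient
    })
    structure(list(tiles = tiles, gradient = gradient, dim = dim),
              class = "tile_stack")
  })
}

#' Clip ultra-dark pixels up to a brightness floor
#'
#' Pixels strictly below the `lower_pct` percentile of the tile are raised
#' to `floor_frac` of the dynamic-range maximum (but never lowered), the
#' usual remedy for ultra-dark electron-dense artifacts such as epoxy
#' creases before flat-field correction. "10% brightness" is interpreted as
#' a fraction of the dtype dynamic range: 25.5 for 8-bit data, 0.1 for
#' unit-range floats.
#'
#' A constant tile has no pixel strictly below its own percentile and is
#' returned unchanged; the operation is idempotent.
#'
#' @param tile Numeric matrix.
#' @param lower_pct Percentile below which pixels are clipped (0-100).
#' @param floor_frac Floor as a fraction of the dynamic-range maximum.
#' @param range_max Dynamic-range maximum. `NULL` infers it from the data:
#'   1 if all values are <= 1, else 255 if <= 255, else 65535.
#' @return Matrix of the same shape, elementwise >= the input.
#' @examples
#' ramp <- matrix(0:255, 16, 16)
#' min(clip_dark(ramp))  # 25.5
#' @export
clip_dark <- function(tile, lower_pct = 10, floor_frac = 0.10,
                      range_max = NULL) {
  if (length(tile) == 0) stop("empty tile")
  if (lower_pct < 0 || lower_pct > 100) stop("lower_pct must be in [0, 100]")
  if (is.null(range_max))
    range_max <- if (max(tile) <= 1) 1 else if (max(tile) <= 255) 255 else 65535
  floor_val <- floor_frac * range_max
  thresh <- quantile(tile, lower_pct / 100, names = FALSE)
  out <- tile
  below <- out < thresh
  out[below] <- pmax(out[below], floor_val)
  out
}

#' Flat-field correct a tile stack
#'
#' Removes the brightness pattern shared across tiles: the pixelwise mean
#' map of the stack is normalized by its own global mean, and every tile is
#' divided by that normalized map,
#' \deqn{\bar R = \frac{1}{n}\sum_i R_i, \qquad
#'       C_i = \frac{R_i}{\bar R / \mu_{\bar R}}.}
#' The pixelwise mean of the corrected tiles is the constant
#' \eqn{\mu_{\bar R}} at every pixel, and the operation is equivariant
#' under a common rescaling of all tiles.
#'
#' @param stack A `tile_stack`, a list of same-shape matrices, or a 3-D
#'   array (tiles along the third margin).
#' @return Object of the same organization with corrected tiles; for
#'   list/`tile_stack` input a `tile_stack` whose `tiles` are corrected and
#'   which carries `mean_map` and `global_mean`.
#' @export
flat_field_correct <- function(stack) {
  tiles <- if (inherits(stack, "tile_stack")) stack$tiles
           else if (is.array(stack) && length(dim(stack)) == 3)
             lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
           else stack
  n <- length(tiles)
  if (n < 2) stop("flat-field correction needs at least 2 tiles")
  d <- dim(tiles[[1]])
  if (!all(vapply(tiles, function(t) identical(dim(t), d), logical(1))))
    stop("all tiles must share one shape")
  mean_map <- Reduce(`+`, tiles) / n
  if (any(mean_map <= 0)) {
    bad <- which(mean_map <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("mean map is not strictly positive at pixel (%d, %d)",
                 bad[1], bad[2]))
  }
  mu <- mean(mean_map)
  norm_map <- mean_map / mu
  corrected <- lapply(tiles, function(t) t / norm_map)
  structure(list(tiles = corrected, gradient = NULL, dim = d,
                 mean_map = mean_map, global_mean = mu),
            class = "tile_stack")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement of a tile, delegated to the CLAHE
#' implementation in \pkg{EBImage}. The kernel size in pixels is converted
#' to the tile-grid resolution CLAHE uses internally. Input is rescaled to
#' [0, 1] before equalization and the output is clamped to [0, 1].
#'
#' @param tile Numeric matrix.
#' @param kernel_px Contextual-region (kernel) size in pixels; must not
#'   exceed either tile dimension.
#' @param clip_limit CLAHE clip limit (passed to `EBImage::clahe`).
#' @return Matrix in [0, 1], same shape.
#' @export
equalize_clahe <- function(tile, kernel_px = 1000, clip_limit = 2) {
  if (length(tile) == 0) stop("empty tile")
  if (kernel_px > nrow(tile) || kernel_px > ncol(tile))
    stop("kernel larger than tile")
  rng <- range(tile)
  if (diff(rng) == 0) return(matrix(0.5, nrow(tile), ncol(tile)))
  x <- (tile - rng[1]) / diff(rng)
  nx <- max(2L, round(ncol(x) / kernel_px))
  ny <- max(2L, round(nrow(x) / kernel_px))
  # EBImage images are (x, y) = (col, row): transpose in and out
  img <- EBImage::Image(t(x))
  out <- EBImage::clahe(img, nx = nx, ny = ny, limit = clip_limit)
  res <- t(EBImage::imageData(out))
  pmin(pmax(res, 0), 1)
}
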