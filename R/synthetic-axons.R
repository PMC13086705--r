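#' Draw axon diameters from the connective-like mixture distribution
#'
#' Diameters are drawn from a truncated lognormal body plus a small
#' "giant axon" lognormal tail, calibrated so the default mixture has a
#' mean near 0.99 um and a median near 0.69 um with support truncated to
#' the biophysically observed range 0.1-15 um (thermal-noise floor to
#' packing-limited giants).
#'
#' @param n Number of diameters.
#' @param body_meanlog,body_sdlog Lognormal parameters of the main body.
#'   Defaults: `log(0.69)` (median 0.69 um) and 0.64 (body mean 0.85 um, so
#'   the 2% giant tail brings the mixture mean to ~0.99 um).
#' @param giant_frac Mixture weight of the giant-axon tail (default 0.02).
#' @param giant_meanlog,giant_sdlog Lognormal parameters of the tail
#'   (default centered near 8 um).
#' @param range_um Truncation interval, um.
#' @param seed Optional RNG seed.
#' @return Numeric vector of diameters, um.
#' @export
draw_axon_diameters <- function(n, body_meanlog = log(0.69), body_sdlog = 0.64,
                                giant_frac = 0.02, giant_meanlog = log(8),
                                giant_sdlog = 0.25, range_um = c(0.1, 15),
                                seed = NULL) {
  stopifnot(n >= 0, length(range_um) == 2, range_um[1] > 0)
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    is_giant <- runif(n) < giant_frac
    d <- numeric(n)
    draw_trunc <- function(m, meanlog, sdlog) {
      out <- numeric(0)
      while (length(out) < m) {
        x <- rlnorm(2 * m + 10, meanlog, sdlog)
        out <- c(out, x[x >= range_um[1] & x <= range_um[2]])
      }
      out[seq_len(m)]
    }
    d[!is_giant] <- draw_trunc(sum(!is_giant), body_meanlog, body_sdlog)
    d[is_giant] <- draw_trunc(sum(is_giant), giant_meanlog, giant_sdlog)
    d
  })
}

#' Generate a ground-truth axon population, optionally rendered as a mask
#'
#' Places `n` non-overlapping circular axon cross-sections in a rectangular
#' hemiconnective-like region and reports their true centers and diameters.
#' Diameters follow [draw_axon_diameters()]; under the `"gradient"` profile
#' the body lognormal's log-mean decreases linearly with depth so dorsal
#' (shallow) axons are larger than ventral (deep) ones, emulating the
#' dorsoventral size gradient of real connectives. Coordinates put the
#' origin at the dorsal-medial corner: depth increases ventrally, span
#' laterally.
#'
#' Placement is random sequential adsorption with a grid-accelerated
#' neighbor search; axons are placed largest-first. The region is sized so
#' axons fill `fill_fraction` of it.
#'
#' @param n Number of axons (>= 0).
#' @param profile `"default"` (no depth trend) or `"gradient"`.
#' @param pixel_nm Pixel size used when rendering, nm/px.
#' @param seed Optional RNG seed.
#' @param render If `TRUE`, also rasterize the population as a label mask
#'   (integer matrix; rows = depth, cols = span; 0 = background).
#' @param fill_fraction Target area fraction of axons in the region.
#' @param aspect Depth:span ratio of the region.
#' @param gradient_strength For the gradient profile: total drop in the
#'   body log-mean from the dorsal to the ventral edge (natural-log units).
#' @param ... Passed to [draw_axon_diameters()].
#' @return A list of class `axon_population`: `table` (data frame with
#'   `axon`, `cx_um` span, `cy_um` depth, `d_um`, `depth_band` quartile
#'   label), `span_um`, `depth_um`, `pixel_nm`, and `mask` (or `NULL`).
#' @examples
#' pop <- generate_axon_population(50, seed = 1)
#' mean(pop$table$d_um)
#' @export
generate_axon_population <- function(n, profile = c("default", "gradient"),
                                     pixel_nm = 50, seed = NULL, render = FALSE,
                                     fill_fraction = 0.3, aspect = 1.5,
                                     gradient_strength = log(6), ...) {
  profile <- match.arg(profile)
  stopifnot(n >= 0, pixel_nm > 0)
  if (n == 0) {
    tab <- data.frame(axon = integer(0), cx_um = numeric(0),
                      cy_um = numeric(0), d_um = numeric(0),
                      depth_band = integer(0))
    mask <- if (render) matrix(0L, 1, 1) else NULL
    return(structure(list(table = tab, span_um = 0, depth_um = 0,
                          pixel_nm = pixel_nm, mask = mask),
                     class = "axon_population"))
  }

  with_seed(seed, {
    depth_frac <- runif(n)
    if (profile == "gradient") {
      # dorsal (depth_frac ~ 0) large, ventral small; keep the giant tail
      dots <- list(...)
      base_meanlog <- if (!is.null(dots$body_meanlog)) dots$body_meanlog else log(0.69)
      dots$body_meanlog <- NULL
      d <- vapply(depth_frac, function(f) {
        do.call(draw_axon_diameters,
                c(list(1, body_meanlog = base_meanlog +
                         gradient_strength * (0.5 - f)), dots))
      }, numeric(1))
    } else {
      d <- draw_axon_diameters(n, ...)
    }

    total_area <- sum(pi * (d / 2)^2)
    region_area <- total_area / fill_fraction
    span_um <- sqrt(region_area / aspect)
    depth_um <- region_area / span_um

    ord <- order(d, decreasing = TRUE)  # place giants first
    r <- d[ord] / 2
    target_depth <- depth_frac[ord] * depth_um
    cx <- cy <- numeric(n)
    cell <- max(d) / 2 + max(r)  # neighbor search radius bound
    ncx <- max(1L, ceiling(span_um / cell))
    ncy <- max(1L, ceiling(depth_um / cell))
    grid <- vector("list", ncx * ncy)
    cell_of <- function(x, y) {
      ix <- pmin(ncx, pmax(1L, ceiling(x / cell)))
      iy <- pmin(ncy, pmax(1L, ceiling(y / cell)))
      (iy - 1L) * ncx + ix
    }
    max_tries <- 2000L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, r[i], span_um - r[i])
        y <- if (profile == "gradient")
          min(max(target_depth[i] + rnorm(1, sd = depth_um / 20), r[i]),
              depth_um - r[i])
        else runif(1, r[i], depth_um - r[i])
        ix <- min(ncx, max(1L, ceiling(x / cell)))
        iy <- min(ncy, max(1L, ceiling(y / cell)))
        ixs <- unique(pmin(ncx, pmax(1L, ix + (-1:1))))
        iys <- unique(pmin(ncy, pmax(1L, iy + (-1:1))))
        neigh <- unlist(grid[as.vector(outer(ixs, (iys - 1L) * ncx, "+"))])
        ok <- TRUE
        if (length(neigh)) {
          dist2 <- (cx[neigh] - x)^2 + (cy[neigh] - y)^2
          ok <- all(dist2 > (r[neigh] + r[i])^2)
        }
        if (ok) {
          cx[i] <- x; cy[i] <- y
          ci <- cell_of(x, y)
          grid[[ci]] <- c(grid[[ci]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("packing failure: could not place axon %d of %d after %d tries",
                     i, n, max_tries))
    }
    r_all <- r
    tab <- data.frame(axon = seq_len(n), cx_um = cx, cy_um = cy,
                      d_um = 2 * r_all)
    tab <- tab[order(tab$cy_um), ]
    tab$axon <- seq_len(n)
    rownames(tab) <- NULL
    tab$depth_band <- as.integer(cut(tab$cy_um, breaks = 4, labels = FALSE))

    mask <- NULL
    if (render)
      mask <- render_axon_mask(tab, span_um = span_um, depth_um = depth_um,
                               pixel_nm = pixel_nm)
    structure(list(table = tab, span_um = span_um, depth_um = depth_um,
                   pixel_nm = pixel_nm, mask = mask),
              class = "axon_population")
  })
}

#' Rasterize circular axon cross-sections into a label mask
#'
#' @param table Data frame with `cx_um`, `cy_um`, `d_um` (and optionally
#'   `axon` labels; row order otherwise).
#' @param span_um,depth_um Region extent, um (defaults: tight bounding box).
#' @param pixel_nm Pixel size, nm/px.
#' @return Integer label matrix (rows = depth, cols = span), background 0.
#'   A pixel belongs to a disk when its center lies within the disk radius.
#' @export
render_axon_mask <- function(table, span_um = NULL, depth_um = NULL,
                             pixel_nm = 50) {
  stopifnot(pixel_nm > 0)
  px_um <- pixel_nm / 1000
  r_um <- table$d_um / 2
  if (is.null(span_um)) span_um <- max(table$cx_um + r_um, 0)
  if (is.null(depth_um)) depth_um <- max(table$cy_um + r_um, 0)
  ncol_px <- max(1L, ceiling(span_um / px_um))
  nrow_px <- max(1L, ceiling(depth_um / px_um))
  mask <- matrix(0L, nrow_px, ncol_px)
  labels <- if (!is.null(table$axon)) table$axon else seq_len(nrow(table))
  for (i in seq_len(nrow(table))) {
    r_px <- r_um[i] / px_um
    cx_px <- table$cx_um[i] / px_um
    cy_px <- table$cy_um[i] / px_um
    cols <- max(1, floor(cx_px - r_px)):min(ncol_px, ceiling(cx_px + r_px) + 1)
    rows <- max(1, floor(cy_px - r_px)):min(nrow_px, ceiling(cy_px + r_px) + 1)
    # pixel centers at (index - 0.5)
    dy2 <- (rows - 0.5 - cy_px)^2
    dx2 <- (cols - 0.5 - cx_px)^2
    inside <- outer(dy2, dx2, "+") <= r_px^2
    sub <- mask[rows, cols, drop = FALSE]
    sub[inside] <- as.integer(labels[i])
    mask[rows, cols] <- sub
  }
  mask
}

#' Generate a synthetic axon-diameter / sheath-thickness dataset
#'
#' Draws `(d, t)` pairs following the allometric law
#' `log10(t) = slope * log10(d) + intercept + N(0, sd_log10^2)`, with
#' `log10(d)` uniform over the log10 of `d_range_um`. Optionally an extra
#' high-variance regime is injected for axons below 2 um, mimicking small
#' axons sharing single glial processes (where thickness decouples from
#' diameter).
#'
#' @param n Number of axons.
#' @param slope,intercept Parameters of the log10-log10 scaling law
#'   (defaults 1.12 and -0.45, the near-isometric regime of connective
#'   ensheathing glia).
#' @param sd_log10 Gaussian noise SD in log10 space.
#' @param d_range_um Diameter range, um; log10(d) is uniform over it.
#' @param small_axon_noise Extra log10 noise SD added below 2 um (0 =
#'   disabled).
#' @param seed Optional RNG seed.
#' @return Data frame with `axon`, `d_um`, `t_um`.
#' @examples
#' tab <- generate_sheath_dataset(137, seed = 1)
#' fit_scaling(tab)
#' @export
generate_sheath_dataset <- function(n = 137, slope = 1.12, intercept = -0.45,
                                    sd_log10 = 0.05,
                                    d_range_um = c(10^0.35, 10^1.1),
                                    small_axon_noise = 0, seed = NULL) {
  stopifnot(n >= 1, all(d_range_um > 0), all(d_range_um <= 20))
  with_seed(seed, {
    log_d <- runif(n, log10(d_range_um[1]), log10(d_range_um[2]))
    noise <- rnorm(n, 0, sd_log10)
    small <- 10^log_d <= 2
    if (small_axon_noise > 0 && any(small))
      noise[small] <- noise[small] + rnorm(sum(small), 0, small_axon_noise)
    log_t <- slope * log_d + intercept + noise
    data.frame(axon = seq_len(n), d_um = 10^log_d, t_um = 10^log_t)
  })
}

#' Generate unpaired velocity and diameter samples linked by a power law
#'
#' Emulates the situation where axon diameters (from microscopy) and
#' conduction velocities (from extracellular recording) are measured on the
#' same population but never on the same axon: diameters are drawn from a
#' truncated lognormal, and velocities are `d^k` with multiplicative
#' lognormal noise, computed from the same draws but returned as two
#' unpaired vectors.
#'
#' @param n Number of samples in each vector.
#' @param k True scaling exponent (`v = d^k`).
#' @param meanlog,sdlog Natural-log parameters of the diameter lognormal.
#' @param d_min_um Lower truncation: only diameters above this enter
#'   (default 3 um, the size below which extracellular sampling misses
#'   axons).
#' @param velocity_noise SD of the multiplicative lognormal noise on
#'   velocity (0.05 = ~5% noise).
#' @param seed Optional RNG seed.
#' @return List with `diameters` (um) and `velocities` (m/s).
#' @export
generate_velocity_diameter_data <- function(n = 150, k = 0.64, meanlog = 1.2,
                                            sdlog = 0.35, d_min_um = 3,
                                            velocity_noise = 0.05,
                                            seed = NULL) {
  stopifnot(n >= 1, k > 0)
  with_seed(seed, {
    d <- numeric(0)
    while (length(d) < n) {
      x <- rlnorm(2 * n + 10, meanlog, sdlog)
      d <- c(d, x[x > d_min_um])
    }
    d <- d[seq_len(n)]
    v <- d^k * exp(rnorm(n, 0, velocity_noise))
    list(diameters = d, velocities = v)
  })
}
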