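#' Remove small objects from a binary mask
#'
#' Deletes every connected foreground object whose pixel area is strictly
#' less than `min_area_px`, the standard cleanup applied to segmentation
#' masks before measurement (400 px^2 is about 0.01 um^2 at 5.1 nm/px,
#' well below the smallest real axon cross-section).
#'
#' @param mask Binary matrix (logical or 0/1).
#' @param min_area_px Minimum object area in pixels; objects with area
#'   `>= min_area_px` are kept untouched.
#' @param connectivity 4 or 8 (see [label_components()]).
#' @return Binary (integer 0/1) matrix of the same shape.
#' @examples
#' m <- matrix(0L, 30, 30); m[2:21, 2:21] <- 1L  # 400 px
#' sum(remove_small(m))  # kept
#' @export
remove_small <- function(mask, min_area_px = 400, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab %in% keep] <- 1L
  out
}

#' Connected-component labeling
#'
#' Labels each maximal connected foreground region of a binary mask with a
#' distinct positive integer (background 0). Default connectivity is 8
#' (diagonal neighbors connect), which avoids splitting thin diagonal necks
#' between touching regions.
#'
#' @param mask Binary matrix (any nonzero value is foreground).
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal).
#' @return Integer label matrix of the same shape.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  label_components_cpp(m, as.integer(connectivity))
}

#' Measure per-axon morphometrics from a label mask
#'
#' Computes, for every labeled object, its pixel area, physical area,
#' centroid, and equivalent-circle diameter \eqn{d = 2\sqrt{A/\pi}} (the
#' diameter of a circle with the same area; a lower bound on the maximum
#' edge-to-edge length for non-circular sections). Coordinates use the
#' dorsal-medial corner as origin: `cy_um` (depth) increases ventrally down
#' the rows, `cx_um` (span) laterally across the columns; centroids are
#' unweighted pixel-center means.
#'
#' @param label_mask Integer label matrix (e.g. from [label_components()]).
#' @param pixel_nm Pixel size in nm (default 5.1, typical high-resolution
#'   TEM mosaics).
#' @return An `axon_table`: data frame with `label`, `area_px`, `area_um2`,
#'   `cx_um`, `cy_um`, `d_um`; attribute `pixel_nm`.
#' @examples
#' m <- matrix(0L, 20, 40); m[3:8, 3:8] <- 1L; m[12:18, 20:30] <- 2L
#' measure_axons(m, pixel_nm = 1000)
#' @export
measure_axons <- function(label_mask, pixel_nm = 5.1) {
  if (pixel_nm <= 0) stop("pixel size must be positive")
  px_um <- pixel_nm / 1000
  labs <- sort(unique(label_mask[label_mask > 0]))
  if (length(labs) == 0)
    return(structure(data.frame(label = integer(0), area_px = integer(0),
                                area_um2 = numeric(0), cx_um = numeric(0),
                                cy_um = numeric(0), d_um = numeric(0)),
                     pixel_nm = pixel_nm, class = c("axon_table", "data.frame")))
  idx <- which(label_mask > 0)
  l <- label_mask[idx]
  row <- (idx - 1) %% nrow(label_mask) + 1
  col <- (idx - 1) %/% nrow(label_mask) + 1
  area_px <- as.vector(tapply(l, l, length))
  cy <- as.vector(tapply(row, l, mean))   # depth, rows
  cx <- as.vector(tapply(col, l, mean))   # span, cols
  area_um2 <- area_px * px_um^2
  tab <- data.frame(label = labs,
                    area_px = as.integer(area_px),
                    area_um2 = area_um2,
                    cx_um = (cx - 0.5) * px_um,
                    cy_um = (cy - 0.5) * px_um,
                    d_um = 2 * sqrt(area_um2 / pi))
  structure(tab, pixel_nm = pixel_nm, class = c("axon_table", "data.frame"))
}

#' Axon area fraction of the hemiconnective cross-section
#'
#' Ratio of the summed axon areas to the area of the convex hull of the
#' axon centroids, the hull serving as the estimate of total
#' hemiconnective cross-sectional area.
#'
#' @param table An `axon_table` (needs `area_um2`, `cx_um`, `cy_um`).
#' @return Scalar fraction (> 0; can exceed 1 only when the centroid hull
#'   underestimates the true tissue outline).
#' @export
area_fraction <- function(table) {
  if (nrow(table) < 3) stop("degenerate hull: need at least 3 centroids")
  h <- chull(table$cx_um, table$cy_um)
  if (length(h) < 3) stop("degenerate hull: centroids are collinear")
  hull_area <- polygon_area(cbind(table$cx_um[h], table$cy_um[h]))
  if (hull_area <= 0) stop("degenerate hull: zero area")
  sum(table$area_um2) / hull_area
}

#' Spatial distribution of axon centroids
#'
#' Bins axon centroids along the dorsoventral depth or mediolateral span
#' axis and collects the diameter samples falling in each slice, the raw
#' material for depth-profile histograms and per-slice diameter
#' distributions.
#'
#' @param table An `axon_table`.
#' @param axis `"depth"` (bins over `cy_um`) or `"span"` (over `cx_um`).
#' @param n_bins Number of equal-width bins (>= 1).
#' @return List of class `spatial_distribution`: `axis`, `edges_um`
#'   (length `n_bins + 1`), `counts` (sums to `nrow(table)`), `diameters`
#'   (list of per-slice diameter vectors).
#' @export
spatial_histograms <- function(table, axis = c("depth", "span"), n_bins = 10) {
  axis <- match.arg(axis)
  stopifnot(n_bins >= 1)
  x <- if (axis == "depth") table$cy_um else table$cx_um
  if (nrow(table) == 0) {
    edges <- seq(0, 1, length.out = n_bins + 1)
    return(structure(list(axis = axis, edges_um = edges,
                          counts = rep(0L, n_bins),
                          diameters = rep(list(numeric(0)), n_bins)),
                     class = "spatial_distribution"))
  }
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  diameters <- lapply(seq_len(n_bins), function(b) table$d_um[bin == b])
  structure(list(axis = axis, edges_um = edges, counts = counts,
                 diameters = diameters),
            class = "spatial_distribution")
}

#' Summarize an axon diameter distribution
#'
#' Mean, median, range, counts of axons strictly larger than each
#' threshold, and a Shapiro-Wilk normality test on `ln(d)` (lognormality
#' check). The test is delegated to [stats::shapiro.test()] and needs
#' 3-5000 values; outside that range the summary is returned with the test
#' fields `NA` and `test_note` set.
#'
#' @param table An `axon_table` (or anything with a `d_um` column).
#' @param thresholds_um Diameter thresholds for the ">" counts (default 5
#'   and 8 um, the "giant axon" sizes of interest).
#' @return List: `n`, `mean_um`, `median_um`, `min_um`, `max_um`,
#'   `count_above` (named), `shapiro_w`, `shapiro_p`, `test_note`.
#' @export
summarize_diameters <- function(table, thresholds_um = c(5, 8)) {
  d <- table$d_um
  counts <- vapply(thresholds_um, function(th) sum(d > th), integer(1))
  names(counts) <- paste0(">", thresholds_um, "um")
  out <- list(n = length(d), mean_um = mean(d), median_um = median(d),
              min_um = if (length(d)) min(d) else NA_real_,
              max_um = if (length(d)) max(d) else NA_real_,
              count_above = counts,
              shapiro_w = NA_real_, shapiro_p = NA_real_, test_note = NULL)
  if (length(d) >= 3 && length(d) <= 5000) {
    sw <- shapiro.test(log(d))
    out$shapiro_w <- unname(sw$statistic)
    out$shapiro_p <- sw$p.value
  } else {
    out$test_note <- sprintf("Shapiro-Wilk on ln(d) skipped: n = %d outside 3..5000",
                             length(d))
  }
  out
}

#' Total axon count from a hemiconnective count
#'
#' Doubles a single-hemiconnective count under the bilateral-symmetry
#' assumption (both lateral halves carry the same number of axons).
#'
#' @param hemicount Non-negative axon count in one hemiconnective.
#' @return Integer `2 * hemicount`, with attribute
#'   `assumption = "bilateral symmetry"`.
#' @examples
#' total_count(4437)  # 8874
#' @export
total_count <- function(hemicount) {
  stopifnot(hemicount >= 0)
  structure(2L * as.integer(hemicount), assumption = "bilateral symmetry")
}
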