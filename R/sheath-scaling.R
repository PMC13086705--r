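#' Polygon area by the shoelace (trapezoid) rule
#'
#' Absolute enclosed area of a simple polygon given its vertex coordinates,
#' via trapezoidal integration of the boundary; invariant to vertex order
#' (orientation) and starting vertex.
#'
#' @param coords Two-column matrix (or data frame) of `(x, y)` vertices, in
#'   order around the boundary; the polygon is closed implicitly.
#' @return Scalar area (same squared units as the coordinates).
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
#' @export
polygon_area <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("a polygon needs at least 3 vertices")
  x <- coords[, 1]; y <- coords[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Sheath thickness from axon and fiber areas
#'
#' Thickness of the glial sheath around an axon, computed as the difference
#' between the equivalent-circle radius of the whole fiber (axon plus
#' sheath) and that of the axon alone:
#' \eqn{t = \sqrt{A_{fiber}/\pi} - \sqrt{A_{axon}/\pi}}.
#'
#' @param axon_area Axon cross-sectional area (>= 0).
#' @param fiber_area Fiber (axon + sheath) area; must be >= `axon_area` —
#'   a smaller fiber area signals swapped or misassigned traces.
#' @return Thickness in the linear unit of the areas (vectorized).
#' @examples
#' sheath_thickness(pi, 4 * pi)  # radius 2 - radius 1 = 1
#' @export
sheath_thickness <- function(axon_area, fiber_area) {
  if (any(axon_area < 0)) stop("axon_area must be non-negative")
  if (any(fiber_area < axon_area))
    stop("fiber area smaller than axon area: check trace assignment")
  sqrt(fiber_area / pi) - sqrt(axon_area / pi)
}

#' Read paired membrane traces and build a sheath table
#'
#' Reads a long-format CSV of manually traced membrane polygons — one ring
#' for the axon plasma membrane and one for the outermost sheath layer per
#' axon — and converts each pair into areas, equivalent diameters and
#' sheath thickness.
#'
#' @param path CSV with columns `axon_id`, `ring` (`"axon"` or `"fiber"`),
#'   `vertex_index`, `x`, `y` (um).
#' @return Data frame with `axon`, `axon_area_um2`, `fiber_area_um2`,
#'   `d_um` (axon equivalent diameter), `t_um` (sheath thickness).
#' @export
read_sheath_traces <- function(path) {
  tr <- read.csv(path)
  need <- c("axon_id", "ring", "vertex_index", "x", "y")
  if (!all(need %in% names(tr)))
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(tr$axon_id)
  rows <- lapply(ids, function(id) {
    sub <- tr[tr$axon_id == id, ]
    get_ring <- function(ring) {
      r <- sub[sub$ring == ring, ]
      if (nrow(r) < 3) stop(sprintf("axon %s: ring '%s' has < 3 vertices", id, ring))
      r <- r[order(r$vertex_index), ]
      polygon_area(cbind(r$x, r$y))
    }
    a_axon <- get_ring("axon")
    a_fiber <- get_ring("fiber")
    data.frame(axon = id, axon_area_um2 = a_axon, fiber_area_um2 = a_fiber,
               d_um = 2 * sqrt(a_axon / pi),
               t_um = sheath_thickness(a_axon, a_fiber))
  })
  do.call(rbind, rows)
}

#' Fit the log-log axon-diameter / sheath-thickness scaling
#'
#' Ordinary least squares of `log10(t)` on `log10(d)` restricted to axons
#' with diameter strictly above `d_min_um`. Small axons are excluded
#' because several of them frequently share a single glial process, so
#' their sheath thickness decouples from their diameter; above ~2 um the
#' relation is close to isometric. The 95% CI on the slope uses the
#' analytic OLS standard error with a t quantile at `n - 2` df.
#'
#' Rows with `t = 0` among the *excluded* small axons are dropped silently
#' with the rest of the filter; a `t <= 0` among the rows that would enter
#' the fit is an error (the log is undefined and such a row indicates a
#' tracing bug, not a small-axon regime).
#'
#' @param table Data frame with `d_um` and `t_um` (e.g. from
#'   [generate_sheath_dataset()] or [read_sheath_traces()]).
#' @param d_min_um Diameter filter: only `d > d_min_um` rows are fit.
#' @param level Confidence level for the slope interval.
#' @return List of class `scaling_fit`: `slope`, `intercept`,
#'   `slope_ci_halfwidth`, `slope_se`, `level`, `n_used`, `n_total`,
#'   `d_min_um`, `model` (the `lm` fit).
#' @examples
#' tab <- generate_sheath_dataset(137, sd_log10 = 0, seed = 1)
#' fit_scaling(tab)$slope  # 1.12 exactly
#' @export
fit_scaling <- function(table, d_min_um = 2, level = 0.95) {
  keep <- table$d_um > d_min_um
  sub <- table[keep, ]
  if (any(sub$t_um <= 0))
    stop("non-positive sheath thickness among rows with d > d_min: log undefined")
  if (nrow(sub) < 3) stop("need at least 3 rows with d > d_min to fit")
  fit <- lm(log10(t_um) ~ log10(d_um), data = sub)
  se <- summary(fit)$coefficients[2, 2]
  hw <- qt(1 - (1 - level) / 2, df = nrow(sub) - 2) * se
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_ci_halfwidth = hw, slope_se = se, level = level,
                 n_used = nrow(sub), n_total = nrow(table),
                 d_min_um = d_min_um, model = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling fit (d > %g um, n = %d of %d):\n", x$d_min_um,
              x$n_used, x$n_total))
  cat(sprintf("  log10(t) = %.3f * log10(d) + %.3f   (slope %.2f +/- %.2f, %g%% CI)\n",
              x$slope, x$intercept, x$slope, x$slope_ci_halfwidth,
              100 * x$level))
  invisible(x)
}
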