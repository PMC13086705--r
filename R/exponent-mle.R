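#' Implied diameters from velocities under a candidate exponent
#'
#' Inverts the power law `v = d^k` for a candidate exponent:
#' `d_est = |v|^(1/k)`. Ascending and descending velocities are pooled as
#' magnitudes.
#'
#' @param velocities Nonzero velocities, m/s (sign ignored).
#' @param k Candidate exponent (> 0).
#' @return Numeric vector of implied diameters.
#' @examples
#' transform_velocities(4, 0.5)  # 16
#' @export
transform_velocities <- function(velocities, k) {
  if (k <= 0) stop("k must be positive")
  if (any(velocities == 0)) stop("zero velocity has no implied diameter")
  abs(velocities)^(1 / k)
}

# Gaussian-kernel KDE evaluated at query points; Silverman bandwidth by
# default, floored so repeated samples cannot give bw = 0
kde_pdf <- function(query, samples, bw = NULL) {
  if (is.null(bw)) bw <- stats::bw.nrd0(samples)
  if (!is.finite(bw) || bw <= 0) bw <- max(1e-8, stats::sd(samples) / 10, 1e-8)
  colMeans(dnorm(outer(samples, query, "-"), sd = bw))
}

#' Log-likelihood of an exponent linking velocity and diameter samples
#'
#' Scores a candidate exponent `k` against *unpaired* velocity and diameter
#' samples: velocities are transformed to implied diameters
#' `d_est = |v|^(1/k)`, a Gaussian-kernel density estimate (Silverman's
#' rule) is fitted to `d_est`, and the log density is summed over the
#' measured diameters above `d_min_um`. The density is floored at a tiny
#' positive constant before logging so the likelihood is finite everywhere
#' on a grid.
#'
#' Only diameters strictly greater than `d_min_um` (default 3 um) enter the
#' sum, reflecting the prior that extracellular velocity measurements come
#' only from axons that large.
#'
#' @param k Candidate exponent.
#' @param velocities Nonzero velocities (>= 5).
#' @param diameters Measured diameters, um.
#' @param d_min_um Diameter filter (strict `>`).
#' @param density_floor Lower floor on the KDE density before logging.
#' @return Scalar log-likelihood.
#' @export
exponent_loglik <- function(k, velocities, diameters, d_min_um = 3,
                            density_floor = 1e-300) {
  if (length(velocities) < 5) stop("need at least 5 velocities")
  d <- diameters[diameters > d_min_um]
  if (length(d) < 5) stop("need at least 5 diameters above d_min")
  d_est <- transform_velocities(velocities, k)
  pdf <- kde_pdf(d, d_est)
  sum(log(pmax(pdf, density_floor)))
}

#' Maximum-likelihood exponent linking velocity and diameter distributions
#'
#' Grid search for the exponent `k` in `v = d^k` most likely to link an
#' observed velocity distribution to an observed diameter distribution,
#' when the two are measured on the same population but never on the same
#' axon. The log-likelihood of [exponent_loglik()] is evaluated on a grid
#' over `[k_lo, k_hi]` and the argmax taken; ties break toward the smaller
#' `k` with a warning.
#'
#' @param velocities Nonzero velocities, m/s (magnitudes pooled).
#' @param diameters Measured diameters, um.
#' @param k_lo,k_hi,step Grid over candidate exponents (defaults 0.4, 1.5,
#'   0.005).
#' @param d_min_um Diameter filter (strict `>`), default 3 um.
#' @return Object of class `exponent_fit`: `k_hat`, `k_grid`, `loglik`,
#'   `d_min_um`, `n_velocities`, `n_diameters_used`, `settings`.
#' @examples
#' sim <- generate_velocity_diameter_data(100, k = 0.64, velocity_noise = 0,
#'                                        seed = 1)
#' fit_exponent(sim$velocities, sim$diameters)$k_hat
#' @export
fit_exponent <- function(velocities, diameters, k_lo = 0.4, k_hi = 1.5,
                         step = 0.005, d_min_um = 3) {
  k_grid <- seq(k_lo, k_hi, by = step)
  if (length(k_grid) == 0) stop("empty exponent grid")
  ll <- vapply(k_grid, exponent_loglik, numeric(1),
               velocities = velocities, diameters = diameters,
               d_min_um = d_min_um)
  if (all(!is.finite(ll))) stop("log-likelihood non-finite across the whole grid")
  best <- max(ll, na.rm = TRUE)
  ties <- which(ll == best)
  if (length(ties) > 1)
    warning("log-likelihood tie on the grid; taking the smallest k")
  structure(list(k_hat = k_grid[ties[1]], k_grid = k_grid, loglik = ll,
                 d_min_um = d_min_um, n_velocities = length(velocities),
                 n_diameters_used = sum(diameters > d_min_um),
                 settings = list(k_lo = k_lo, k_hi = k_hi, step = step,
                                 kde = "gaussian", bandwidth = "silverman (nrd0)")),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("exponent fit: k_hat = %.3f on grid [%g, %g] step %g (n_v = %d, n_d = %d, d > %g um)\n",
              x$k_hat, x$settings$k_lo, x$settings$k_hi, x$settings$step,
              x$n_velocities, x$n_diameters_used, x$d_min_um))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% BCa CI: [%.3f, %.3f] (%d bootstrap replicates)\n",
                100 * x$ci_level, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' BCa bootstrap confidence interval for the scaling exponent
#'
#' Bias-corrected and accelerated bootstrap interval for the exponent of
#' [fit_exponent()]. Velocities are resampled with replacement (diameters
#' stay fixed) and the full grid search repeated per replicate; the BCa
#' adjustment (bias from the bootstrap distribution, acceleration from a
#' jackknife over velocities) is computed by \pkg{boot}.
#'
#' @param velocities,diameters As in [fit_exponent()].
#' @param n_boot Number of bootstrap replicates (>= 100; 10,000 for
#'   production use, smaller for quick checks).
#' @param level Confidence level.
#' @param seed RNG seed; the interval is reproducible under it.
#' @param ... Grid and filter settings passed to [fit_exponent()].
#' @return List: `ci` (lo, hi), `k_hat`, `boot_k` (replicate exponents),
#'   `n_boot`, `level`, `degenerate` (TRUE when all replicates agreed and
#'   a collapsed interval was returned).
#' @export
exponent_bca_ci <- function(velocities, diameters, n_boot = 10000,
                            level = 0.95, seed = NULL, ...) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  stat <- function(v, idx) fit_exponent(v[idx], diameters, ...)$k_hat
  k_hat <- stat(velocities, seq_along(velocities))
  with_seed(seed, {
    b <- boot::boot(velocities, stat, R = n_boot)
    if (length(unique(b$t[, 1])) == 1) {
      warning("degenerate bootstrap distribution: all replicates identical; returning a collapsed interval")
      return(list(ci = c(b$t[1, 1], b$t[1, 1]), k_hat = k_hat,
                  boot_k = b$t[, 1], n_boot = n_boot, level = level,
                  degenerate = TRUE))
    }
    ci <- tryCatch(boot::boot.ci(b, conf = level, type = "bca")$bca[1, 4:5],
                   error = function(e) NULL)
    if (is.null(ci)) {
      # acceleration undefined (nearly-degenerate replicates): fall back to
      # a bias-corrected percentile interval
      warning("BCa acceleration undefined for a nearly-degenerate bootstrap; returning a bias-corrected percentile interval")
      t_rep <- b$t[, 1]
      p0 <- (sum(t_rep < k_hat) + 0.5 * sum(t_rep == k_hat)) / length(t_rep)
      if (p0 <= 0 || p0 >= 1) {
        ci <- range(t_rep)
      } else {
        z0 <- qnorm(p0)
        zq <- qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
        ci <- unname(quantile(t_rep, pnorm(2 * z0 + zq), type = 6))
      }
    }
    list(ci = ci, k_hat = k_hat, boot_k = b$t[, 1],
         n_boot = n_boot, level = level, degenerate = FALSE)
  })
}
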