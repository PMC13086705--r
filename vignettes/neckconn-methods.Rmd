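---
title: "Quantifying axon counts and conduction in an insect neck connective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon counts and conduction in an insect neck connective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckconn)
```

## The problem

The neck connective of an insect is the single tract of axons carrying all
neural traffic between brain and body. Two of its properties bound what
the animal's nervous system can do: how *many* axons it contains (a spatial
bottleneck on information) and how *fast* those axons conduct (a temporal
bottleneck on latency). `neckconn` implements the full quantitative chain
needed to measure both from the two standard data sources — transmission
electron microscopy (TEM) mosaics of connective cross-sections, and
multi-shank extracellular recordings along the connective — together with a
synthetic-data module that generates inputs with known ground truth so
every stage can be validated without microscopes or moths.

## TEM tile preprocessing

Raw TEM tiles carry ultra-dark electron-dense artifacts (epoxy creases) and
a brightness pattern shared across all tiles of a mosaic (camera
fixed-pattern noise and illumination gradients). The chain is:

1. **Dark clipping** (`clip_dark`): pixels strictly below the 10th
   percentile of the tile are raised to 10% of the dynamic-range maximum
   (25.5 for 8-bit data). "10% brightness" is interpreted as a fraction of
   the dtype range rather than a percentile value, and the strict-below
   rule makes constant tiles fixed points. One caveat worth knowing: when
   a tile has substantial mass below the floor, raising pixels shifts the
   tile's percentile upward, so a *second* application can raise a further
   thin band of pixels. The operation is intended (and tested) as a
   single-pass cleanup; it is exactly idempotent whenever the floor does
   not exceed the percentile, and on ramps and constants.
2. **Flat-field correction** (`flat_field_correct`): with tiles
   $R_1,\dots,R_n$, the pixelwise mean $\bar R$ is normalized by its global
   mean $\mu_{\bar R}$ and each tile divided by it,
   $C_i = R_i / (\bar R / \mu_{\bar R})$. Two algebraic identities make
   this testable to machine precision: the pixelwise mean of the corrected
   stack equals the constant $\mu_{\bar R}$ everywhere, and the operation
   is equivariant under a common rescaling of the stack. Division is
   guarded: a non-positive mean-map pixel is an error naming the pixel, not
   a silent NaN.
3. **CLAHE** (`equalize_clahe`): contrast-limited adaptive histogram
   equalization, delegated to `EBImage::clahe` with the kernel size in
   pixels converted to CLAHE's tile grid. Input is normalized to $[0,1]$;
   output is clamped there.

The order clip → flat-field → CLAHE matters: clipping before the mean map
keeps artifact pixels from contaminating $\bar R$, and CLAHE last operates
on gradient-free tiles. Clipping is per-tile; the tile, not the assembled
mosaic, is the unit all three operators see.

## Morphometry from label masks

Segmentation and proofreading are upstream of this package; its inputs are
binary or label masks. `remove_small` deletes connected objects below 400
px² (about 0.01 µm² at 5.1 nm/px) with a *strict* less-than, so a 400-px
object survives. `label_components` is a two-pass union-find labeler
(compiled) with selectable 4- or 8-connectivity; 8 is the default so thin
diagonal necks do not split an axon. `measure_axons` converts to physical
units and computes the equivalent-circle diameter
$d = 2\sqrt{A/\pi}$ — a lower bound on the maximum edge-to-edge length for
non-circular profiles. Coordinates place the origin at the dorsal-medial
corner: depth (`cy_um`) increases ventrally, span (`cx_um`) laterally.
Centroids are unweighted pixel means (masks are binary; there is no
intensity to weight by).

Downstream summaries follow the same conventions as the measurements:
`area_fraction` divides total axon area by the area of the convex hull of
centroids (the hull is the estimate of hemiconnective area, so the
fraction can in principle exceed 1 only if the hull underestimates the
tissue outline); `spatial_histograms` bins centroids by depth or span and
returns per-slice diameter samples; `summarize_diameters` counts axons
*strictly* above each threshold and runs a Shapiro–Wilk test on
$\ln d$ (the lognormality check; `stats::shapiro.test` accepts 3–5000
values, outside which the summary is returned flagged instead of erroring);
`total_count` doubles a hemiconnective count under bilateral symmetry and
records that assumption in an attribute.

## Sheath scaling

For the ensheathing-glia analysis, the inputs are manually traced polygon
rings of the axon membrane and the outermost sheath layer. Areas come from
the shoelace (trapezoid) rule (`polygon_area`, orientation-invariant);
thickness is the equivalent-circle radius difference
$t = \sqrt{A_{fiber}/\pi} - \sqrt{A_{axon}/\pi}$, consistent with the
diameter convention of the morphometry module. A fiber area below the axon
area is an error by design: it indicates swapped trace assignment, the
most likely bookkeeping bug in manual tracing.

`fit_scaling` fits $\log_{10} t$ on $\log_{10} d$ by OLS, restricted to
axons strictly larger than 2 µm. Below that size several axons often share
one glial process, so thickness decouples from diameter; above it the
relation is near-isometric. The 95% CI on the slope uses the analytic OLS
standard error with a $t$ quantile at $n-2$ df — the reference analyses do
not name their CI method, and the analytic choice is recorded here so the
number is interpretable. A non-positive thickness among rows that would
enter the fit is an error (the log is undefined); non-positive thickness
among the excluded small axons is simply filtered with the rest.

## Conduction velocity from multi-shank recordings

A spike propagating along the connective reaches the probe's shanks at
times offset by $\Delta x / v$. The estimator follows the
microphone-array style delay-and-ratio approach:

1. **Band-pass** 300–5000 Hz (4th-order Butterworth, forward–backward so
   the filter is zero-phase and cannot bias arrival times), then
   **z-score** each channel so amplitudes are in SD units.
2. **Mean waveforms**: 4 ms windows around each spike, averaged per
   channel. Spikes within half a window of a record edge are dropped with
   a logged count.
3. **Round-robin correction** (`correct_round_robin`): a multiplexed
   headstage samples its channels sequentially — 35 ADC slots at 1.05 MHz
   serve 30 kHz channels — so channel in slot $s$ is acquired $s/f_{adc}$
   late, up to a full sample period across the array. Each mean waveform
   is resampled onto the common frame clock by windowed-sinc (Hann-tapered,
   half-width 32 samples) interpolation; a cubic-spline fallback is
   selectable. Skipping this correction would alias a systematic,
   channel-order-dependent bias directly into $\Delta t$.
4. **Pairwise lags** (`pair_lag`): unnormalized cross-correlation
   $c_{ij}[l] = \sum_t x_i[t+l]\,x_j[t]$ over lags spanning half the
   window each way (channels are z-scored upstream, so no further
   normalization is applied). The lag is refined to sub-sample precision by
   a quadratic fit through the 4 largest correlation values; the fit falls
   back to the discrete argmax when the top-4 lags are non-contiguous, the
   parabola opens upward, or its vertex leaves the lag span — the
   refinement is only meaningful around a single well-formed peak. Because
   the 4 chosen points need not be symmetric about the peak, the refined
   lag of two *identical* waveforms is not exactly zero, only zero within
   the interpolation tolerance (≤ 0.25 samples); the tests assert exactly
   that.
5. **Velocity** (`estimate_velocity`): the mean of $\Delta x / \Delta t$
   over all channel pairs whose mean-waveform peak exceeds 1.5 SD and
   whose axial separation is non-zero (sites within one shank are axially
   co-located and carry no timing information). Pairs with $|\Delta t|$
   below one ADC slot period are unresolvable in time; rather than
   contribute enormous ratios, they are excluded from the mean and counted
   as near-simultaneous in the per-pair ledger. The mean is unweighted, as
   the estimator is defined.

Sign convention: positive $\Delta t_{ij}$ means channel $j$ lags channel
$i$; combined with axial positions, positive velocity means propagation
toward increasing axial coordinate, labelled "ascending". Probe
orientation is not knowable from the data alone, so the convention is
declared in the output metadata rather than assumed.

`observational_bounds` makes the measurement limits explicit: the fastest
resolvable velocity is the maximal baseline over one sample period
(450 µm × 30 kHz = 13.5 m/s for the default geometry) and the slowest is
the baseline over the largest measurable lag, half the window
(450 µm / 2 ms = 0.225 m/s, 0.23 when rounded half-up to two decimals;
both values are reported). Estimates outside the bounds are flagged, never
silently returned. `to_latency` converts velocities to traversal times
over a stated path length (1 cm by default), and `compare_directions`
delegates the ascending-vs-descending comparison to the standard
two-sample Kolmogorov–Smirnov and Shapiro–Wilk implementations.

## The velocity–diameter exponent

Velocities and diameters are measured on the same population but never on
the same axon, so the scaling exponent $k$ in $v = d^k$ cannot come from a
regression. Instead `fit_exponent` asks which $k$ makes the *distribution*
of implied diameters $d_{est} = |v|^{1/k}$ most consistent with the
measured diameter distribution: a Gaussian-kernel KDE is fitted to
$d_{est}$ and the log density summed over measured diameters strictly
greater than 3 µm (extracellular recording samples only large axons — the
same prior applied to the data). The log-likelihood is evaluated on a grid
over $[0.4, 1.5]$; defaults:

* grid step 0.005 (the reference analysis states the range but not the
  resolution; one grid step is also the recovery tolerance the tests use);
* Silverman's rule (`bw.nrd0`) for the KDE bandwidth, recorded in the
  output so fits are comparable — the kernel and bandwidth are otherwise
  free choices;
* density floored at $10^{-300}$ before logging, so the grid search is
  total-ordered even when a diameter falls far outside the KDE support;
* ties broken toward smaller $k$, with a warning.

`exponent_bca_ci` wraps the grid search in a bias-corrected and
accelerated bootstrap: velocities are resampled with replacement
(diameters stay fixed, mirroring which measurement is the scarce one), the
argmax recomputed per replicate over the same fixed grid, and the BCa
adjustment computed by `boot`. Degenerate edge cases are handled rather
than failed on: if every replicate agrees, a collapsed interval is
returned with a warning, and if the replicates are so nearly constant that
the jackknife acceleration is undefined, the interval falls back to a
bias-corrected percentile interval, again with a warning. Both arise for
effectively noiseless data, where the honest answer is "the interval has
(near-)zero width".

## What the synthetic generators emulate — and what they do not

* `generate_axon_population` draws diameters from a truncated lognormal
  body (median 0.69 µm) plus a 2% "giant axon" lognormal tail centered
  near 8 µm, calibrated once so the mixture mean is ~0.99 µm within the
  0.1–15 µm truncation. The `"gradient"` profile makes the body log-mean
  fall linearly with depth (dorsal large, ventral small). Placement is
  grid-accelerated random sequential adsorption, largest first, at a 30%
  fill fraction; rendering draws pixel-center-in-circle disks. Real EM
  content — non-circular profiles, glia, mitochondria, staining texture —
  is deliberately absent: disks on background are exactly what the
  morphometry round-trip needs and nothing more, so passing tests validate
  the measurement chain, not a segmentation model.
* `simulate_recording` places a biphasic difference-of-Gaussians template
  (1.2 ms main lobe, 4 ms support) on each channel at arrival times
  $t_0 + \Delta x / v$, *sampled at each channel's true ADC-slot time*,
  with iid Gaussian noise. It emulates timing structure faithfully and
  amplitude structure crudely (no per-channel amplitude decay, no bursts,
  no overlapping units), so velocity-recovery tests validate the timing
  pipeline, not spike sorting — which is out of scope by design.
* `generate_sheath_dataset` draws $\log_{10} d$ uniform over the traced
  range and applies the scaling law plus Gaussian log-noise; an optional
  extra-variance regime below 2 µm mimics shared glial processes.
* `generate_tile_stack` multiplies independent Gaussian contents by one
  shared gradient — the exact forward model that flat-field correction
  inverts.

All randomness flows through one explicitly passed seed per generator
(`with_seed` restores the caller's RNG state), and the pipeline driver
fans a single master seed out to per-stage seeds deterministically.

## Numerical choices and degenerate inputs

* Eligibility thresholds and filters are strict inequalities wherever the
  reference wording is "greater than" / "less than" (400-px filter, 5 and
  8 µm counts, 1.5 SD amplitude, 2 and 3 µm diameter filters).
* Whitening (`modified_whitening`) uses the symmetric inverse square root
  from an eigendecomposition; non-positive-definite covariances are
  errors, not warnings.
* Zero-variance channels, all-zero waveforms, zero velocities, fiber areas
  below axon areas, empty grids, and degenerate hulls all raise immediate
  errors naming the offending object.
* Floating point is used throughout; quantization happens only on export
  (int16 recordings with a stored scale, 16-bit TIFF masks).

## Problem sizes in the test suite

The validation suite runs on one CPU in minutes, using sizes chosen to
keep Monte-Carlo error well inside the asserted tolerances: velocity
recovery uses 50-spike units at SNR 5 across 0.33–5 m/s; exponent-recovery
bias uses 30 seeds per true exponent at $n = 129$ velocities; BCa coverage
uses 10 datasets at 199 replicates; sheath-slope recovery uses 40 seeds of
the 137-row generator. The acceptance script reruns the two headline
parameter recoveries (exponent and sheath slope) at the reference sample
sizes, 150 and 137.

## Known limitations

* The velocity estimator assumes one dominant template per unit and equal
  amplitude across eligible channels; strongly amplitude-graded or
  overlapping units are the spike sorter's problem, upstream of this
  package.
* The exponent MLE compares distributions, not pairs; it cannot detect
  (say) a diameter-dependent bias of the recording method, and its CI
  reflects velocity resampling only.
* The centroid convex hull underestimates tissue area when axons hug the
  hemiconnective boundary, biasing `area_fraction` upward.
* `shapiro.test`'s 5000-sample cap means very large populations get a
  flagged summary rather than a p-value; subsampling is left to the
  caller.
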