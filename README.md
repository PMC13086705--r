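# neckconn

Quantitative analysis of insect neck connectives — the paired axon tracts
through which all neural traffic between brain and body must pass — from
transmission electron microscopy (TEM) and multi-shank extracellular
recordings.

The package is aimed at quantitative neuroanatomists and
electrophysiologists who want to measure two bottleneck properties of a
connective: how many axons it contains and how large they are (spatial),
and how fast those axons conduct (temporal). It implements:

* **TEM tile preprocessing** — dark-pixel clipping, flat-field correction
  (divide each tile by the stack's normalized pixelwise mean map,
  `C_i = R_i / (R̄ / μ_R̄)`), and contrast-limited adaptive histogram
  equalization.
* **Axon morphometry from label masks** — small-object removal (strict
  400 px² rule), 4/8-connectivity connected-component labeling (compiled),
  per-axon areas, centroids and equivalent-circle diameters
  `d = 2√(A/π)`, convex-hull area fractions, depth/span distributions, and
  diameter summaries with a Shapiro–Wilk lognormality check.
* **Ensheathing-glia scaling** — shoelace polygon areas from membrane
  traces, sheath thickness `t = √(A_fiber/π) − √(A_axon/π)`, and the OLS
  fit of `log10(t)` on `log10(d)` for axons above 2 µm with an analytic
  95% CI on the slope.
* **Conduction velocity from multi-shank arrays** — zero-phase 300–5000 Hz
  band-pass, per-channel z-scoring, diagonal-weighted whitening
  `W_new = αW + (1−α)W_diag`, round-robin ADC timing correction
  (windowed-sinc resampling of each channel onto the common frame clock),
  mean-waveform extraction, pairwise cross-correlation lags with top-4
  quadratic sub-sample refinement, and the estimator
  `V = E(Δx_ij / Δt_ij)` over eligible channel pairs, with explicit
  observational bounds and latency conversion.
* **Velocity–diameter scaling exponent** — for unpaired velocity and
  diameter samples, a grid search over `k ∈ [0.4, 1.5]` maximizing the
  summed log KDE density of implied diameters `d_est = |v|^(1/k)` at the
  measured diameters (> 3 µm), with a BCa bootstrap CI resampling
  velocities.
* **Synthetic data for every stage** — probe geometries, propagating-spike
  recordings with true multiplexer timing skew, axon populations with a
  lognormal body plus giant-axon tail, sheath datasets, and gradient tile
  stacks, all with known ground truth and explicit seeds.

## Worked example

Simulate a 4-shank recording of a 2 m/s unit, run the velocity pipeline,
and check the estimate against the probe's observational bounds:

```r
library(neckconn)

probe <- make_probe(n_shanks = 4, sites_per_shank = 4, shank_spacing_um = 150)
cfg   <- recording_config(duration_s = 2, noise_sd = 1, seed = 11)
rec   <- simulate_recording(probe, unit_spec(2, amplitude_sd = 5, n_spikes = 50), cfg)

proc <- zscore_channels(bandpass(rec))
wf   <- correct_round_robin(extract_mean_waveforms(proc, rec$spike_times[[1]]))
est  <- estimate_velocity(wf, probe, amp_threshold_sd = 1.5)
est
#> velocity estimate: 2.028 m/s (ascending), 96 pair(s) used, 0 near-simultaneous

observational_bounds(probe, fs_hz = 30000, window_ms = 4)
#> $v_max_mps        13.5
#> $v_min_mps        0.225
#> $v_min_printed_mps 0.23

to_latency(est$v_mps, length_m = 0.01)   # ms to traverse a 1 cm connective
#> 4.93
```

The estimator recovers the generating 2 m/s within 1.5% from 50 noisy
spikes; 13.5 and 0.225 m/s are the fastest and slowest velocities this
geometry, sampling rate and window can resolve, so the estimate is
comfortably inside the measurable range.

Fitting the velocity–diameter exponent on unpaired synthetic data:

```r
sim <- generate_velocity_diameter_data(150, k = 0.64, velocity_noise = 0.05, seed = 65)
fit <- fit_exponent(sim$velocities, sim$diameters)
fit$k_hat
#> 0.625
```

With 5% multiplicative velocity noise at n = 150 the grid argmax lands
within a few grid steps of the generating exponent 0.64; noiseless data
recover it exactly to one grid step.

An end-to-end synthetic study (`run_pipeline` / `pipeline_report`) writes
per-stage CSV/JSON tables plus a provenance record that reproduces every
output byte-identically from one master seed.

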