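test_that("probe geometry spans and validation behave", {
  expect_equal(make_probe(4, 4, 150)$max_separation_um, 450)
  expect_equal(make_probe(1, 4, 150)$max_separation_um, 0)
  expect_equal(make_probe(2, 1, 150)$max_separation_um, 150)
  expect_error(make_probe(4, 4, 0), "positive")
  expect_error(make_probe(4, 4, -10), "positive")
  p <- make_probe(4, 4, 150)
  expect_equal(sort(p$channel_map$channel), 1:16)
  expect_false(anyDuplicated(p$acquisition_order) > 0)
  expect_true(all(p$acquisition_order < p$n_slots))
})

test_that("recording config enforces the multiplexer identity", {
  cfg <- recording_config()
  expect_equal(cfg$adc_hz / cfg$n_slots, cfg$fs_hz)
  expect_error(recording_config(fs_hz = 30000, adc_hz = 1e6, n_slots = 35),
               "equal")
})

test_that("simulated arrival-time offsets follow dx / v", {
  probe <- make_probe(4, 4, 150)
  # noiseless, one spike: locate the waveform minimum per channel
  cfg <- recording_config(duration_s = 0.5, noise_sd = 0, seed = 1)
  rec <- simulate_recording(probe, unit_spec(2, 5, n_spikes = 1), cfg)
  t0 <- rec$spike_times[[1]][1]
  fs <- cfg$fs_hz
  slot_s <- probe$acquisition_order / cfg$adc_hz
  arrive <- vapply(seq_len(16), function(ch) {
    k <- which.min(rec$data[, ch]) - 1
    k / fs + slot_s[ch]
  }, numeric(1))
  # first-to-last shank offset should be 450 um / 2 m/s = 225 us,
  # to within one sample plus one ADC slot of discretization
  span_s <- arrive[16] - arrive[1]
  expect_lt(abs(span_s - 225e-6), 1 / fs + 1 / cfg$adc_hz)
  # per-pair offsets match dx / v within one sample of quantization
  dx <- probe$channel_map$x_um - probe$channel_map$x_um[1]
  expect_true(all(abs((arrive - arrive[1]) - dx * 1e-6 / 2) <= 1 / fs + 1e-9))
})

test_that("a simultaneous (infinite-velocity) unit lands at one time on all shanks", {
  probe <- make_probe(4, 4, 150)
  cfg <- recording_config(duration_s = 0.5, noise_sd = 0, seed = 2)
  rec <- simulate_recording(probe, unit_spec(Inf, 5, n_spikes = 1), cfg)
  peaks <- apply(rec$data, 2, which.min)
  expect_lte(diff(range(peaks)), 1)  # identical up to ADC-offset quantization
})

test_that("zero velocity is rejected", {
  expect_error(unit_spec(0), "undefined")
})

test_that("the full estimator recovers a 2 m/s unit from 50 noisy spikes", {
  est <- recover_velocity(2, n_spikes = 50, amplitude = 5, noise_sd = 1,
                          seed = 42)
  expect_lt(abs(est$v_mps - 2) / 2, 0.05)
  expect_identical(est$direction, "ascending")
})

test_that("axon population matches its target distribution", {
  expect_equal(nrow(generate_axon_population(0)$table), 0)
  pop <- generate_axon_population(4437, seed = 7)
  d <- pop$table$d_um
  expect_true(all(d >= 0.1 & d <= 15))
  expect_lt(abs(mean(d) - 0.99) / 0.99, 0.10)
  expect_gt(sum(d > 8), 0)  # the giant tail is populated
  # no overlaps
  n <- nrow(pop$table)
  idx <- sample(n, min(n, 400))
  dd <- as.matrix(dist(pop$table[idx, c("cx_um", "cy_um")]))
  rr <- outer(pop$table$d_um[idx] / 2, pop$table$d_um[idx] / 2, "+")
  diag(dd) <- Inf
  expect_true(all(dd >= rr - 1e-9))
})

test_that("gradient profile gives dorsal-large, ventral-small axons", {
  pop <- generate_axon_population(1200, profile = "gradient", seed = 3)
  sh <- spatial_histograms(
    structure(pop$table, class = c("axon_table", "data.frame")),
    axis = "depth", n_bins = 4)
  med <- vapply(sh$diameters, median, numeric(1))
  expect_true(all(diff(med) < 0))  # depth increases ventrally; sizes shrink
})

test_that("rendered disks are recovered by morphometry within 2 pixels", {
  tab <- data.frame(axon = 1:3, cx_um = c(30, 90, 150), cy_um = c(40, 42, 38),
                    d_um = c(20, 32, 12))
  px_nm <- 1000  # 1 um pixels
  mask <- render_axon_mask(tab, span_um = 180, depth_um = 80, pixel_nm = px_nm)
  meas <- measure_axons(label_components(mask != 0), pixel_nm = px_nm)
  meas <- meas[order(meas$cx_um), ]
  expect_equal(nrow(meas), 3)
  expect_true(all(abs(meas$d_um - tab$d_um) <= 2 * px_nm / 1000))
})

test_that("sheath generator hits its generating law", {
  tab0 <- generate_sheath_dataset(50, slope = 1, intercept = 0, sd_log10 = 0,
                                  seed = 1)
  expect_equal(tab0$t_um, tab0$d_um, tolerance = 1e-12)
  tab <- generate_sheath_dataset(137, slope = 1.12, intercept = -0.45,
                                 sd_log10 = 0, seed = 2)
  fit <- suppressWarnings(fit_scaling(tab))
  expect_equal(fit$slope, 1.12, tolerance = 1e-9)
  expect_equal(fit$intercept, -0.45, tolerance = 1e-9)
  # noisy case: OLS oracle agreement
  tabn <- generate_sheath_dataset(137, sd_log10 = 0.05, seed = 3)
  ols <- lm(log10(t_um) ~ log10(d_um), data = tabn[tabn$d_um > 2, ])
  expect_equal(fit_scaling(tabn)$slope, unname(coef(ols)[2]))
})

test_that("tile stacks carry exactly one shared multiplicative gradient", {
  st <- generate_tile_stack(4, dim = c(32, 32), content_seed = 9)
  # raw tiles correlate with the gradient; corrected tiles at least 10x less
  raw_cor <- mean(vapply(st$tiles, function(t)
    abs(cor(as.vector(t), as.vector(st$gradient))), numeric(1)))
  corr <- flat_field_correct(st)
  cor_cor <- mean(vapply(corr$tiles, function(t)
    abs(cor(as.vector(t), as.vector(st$gradient))), numeric(1)))
  expect_gt(raw_cor / cor_cor, 10)
  # identical contents: every corrected tile is constant
  g <- matrix(seq(0.5, 1.5, length.out = 16), 16, 16, byrow = TRUE)
  content <- matrix(runif(256, 0.3, 0.7), 16, 16)
  same <- lapply(1:3, function(i) content * g)
  cc <- flat_field_correct(same)
  for (t in cc$tiles) expect_lt(diff(range(t / mean(t))), 1e-10)
})

test_that("unpaired velocity/diameter generator respects its truncation and law", {
  sim <- generate_velocity_diameter_data(150, k = 0.64, velocity_noise = 0,
                                         seed = 5)
  expect_true(all(sim$diameters > 3))
  expect_equal(sim$velocities, sim$diameters^0.64, tolerance = 1e-12)
})
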