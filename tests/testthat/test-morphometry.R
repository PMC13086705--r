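test_that("small-object filter is strict at the area threshold", {
  m399 <- matrix(0L, 40, 40)
  m399[2:20, 2:22] <- 1L  # 19 x 21 = 399 px
  expect_equal(sum(remove_small(m399, 400)), 0)
  m400 <- matrix(0L, 40, 40)
  m400[2:21, 2:21] <- 1L  # 400 px
  expect_equal(sum(remove_small(m400, 400)), 400)
  empty <- matrix(0L, 10, 10)
  expect_equal(sum(remove_small(empty, 400)), 0)
  # after filtering, no surviving object is below threshold
  set.seed(3)
  noise <- matrix(rbinom(200 * 200, 1, 0.3), 200, 200)
  filt <- remove_small(noise, 25)
  lab <- label_components(filt)
  if (max(lab) > 0)
    expect_true(all(tabulate(lab[lab > 0]) >= 25))
})

test_that("connected-component labeling honors connectivity", {
  two <- matrix(0L, 10, 10)
  two[2:3, 2:3] <- 1L; two[6:7, 6:7] <- 1L
  expect_equal(max(label_components(two)), 2)
  diag2 <- matrix(0L, 5, 5)
  diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_equal(max(label_components(diag2, 8)), 1)
  expect_equal(max(label_components(diag2, 4)), 2)
  expect_equal(max(label_components(matrix(1L, 6, 6))), 1)
})

test_that("4-connectivity labeling agrees with the EBImage labeler", {
  set.seed(11)
  for (i in 1:6) {
    m <- matrix(rbinom(60 * 60, 1, 0.4), 60, 60)
    ours <- label_components(m, 4)
    ref <- EBImage::bwlabel(m)
    expect_equal(max(ours), max(ref))
    # identical partitions: every component maps 1-1
    expect_equal(length(unique(paste(ours, ref))), max(ours) + 1)
  }
})

test_that("measurement converts pixels to physical units correctly", {
  m <- matrix(0L, 30, 30)
  m[2:21, 2:21] <- 1L  # 400 px
  tab <- measure_axons(m, pixel_nm = 5.1)
  expect_equal(tab$area_um2, 400 * (5.1 / 1000)^2)  # ~0.0104 um^2
  expect_equal(tab$area_um2, 0.0104, tolerance = 0.01)
  expect_equal(tab$d_um, 2 * sqrt(tab$area_um2 / pi))
  # formula identity: area pi um^2 -> d = 2 um
  expect_equal(2 * sqrt(pi / pi), 2)
  expect_error(measure_axons(m, pixel_nm = 0), "positive")
  # rendered disk of radius 100 px: d within 2% of 200 px
  big <- matrix(0L, 220, 220)
  ctr <- 110.5
  for (c in 1:220) {
    dy <- which(((1:220) - ctr)^2 + (c - ctr)^2 <= 100^2)
    if (length(dy)) big[dy, c] <- 1L
  }
  tb <- measure_axons(big, pixel_nm = 1000)
  expect_lt(abs(tb$d_um - 200) / 200, 0.02)
})

test_that("area fraction uses the centroid convex hull", {
  # three unit-diameter disks at the vertices of a triangle of area 100
  tab <- structure(data.frame(label = 1:3,
                              area_px = 1L, area_um2 = pi / 4,
                              cx_um = c(0, 20, 0), cy_um = c(0, 0, 10),
                              d_um = 1),
                   class = c("axon_table", "data.frame"))
  hull_oracle <- shoelace_oracle(c(0, 20, 0), c(0, 0, 10))
  expect_equal(hull_oracle, 100)
  expect_equal(area_fraction(tab), (3 * pi / 4) / 100)
  expect_gt(area_fraction(tab), 0)
  expect_error(area_fraction(tab[1:2, ]), "degenerate")
  collinear <- tab
  collinear$cy_um <- c(0, 0, 0)
  expect_error(area_fraction(collinear), "degenerate")
})

test_that("spatial histograms conserve counts for every binning", {
  pop <- generate_axon_population(500, seed = 13)
  tab <- structure(pop$table, class = c("axon_table", "data.frame"))
  for (nb in c(1, 3, 10, 17)) {
    sh <- spatial_histograms(tab, "depth", nb)
    expect_equal(sum(sh$counts), nrow(tab))
    expect_true(all(diff(sh$edges_um) > 0))
    expect_equal(sum(lengths(sh$diameters)), nrow(tab))
  }
  sh2 <- spatial_histograms(tab, "span", 8)
  expect_equal(sum(sh2$counts), nrow(tab))
  one <- tab[1, , drop = FALSE]
  sh1 <- spatial_histograms(one, "depth", 5)
  expect_equal(sum(sh1$counts > 0), 1)
})

test_that("diameter summaries use strict thresholds and test lognormality", {
  tab <- data.frame(d_um = c(1, 2, 3))
  s <- summarize_diameters(tab)
  expect_equal(s$mean_um, 2)
  expect_equal(s$median_um, 2)
  expect_equal(unname(s$count_above[">5um"]), 0)
  # strictness: a diameter exactly at the threshold is not counted
  expect_equal(unname(summarize_diameters(
    data.frame(d_um = c(5, 5.1)))$count_above[">5um"]), 1)
  # exact lognormal samples rarely reject at alpha = 0.01
  rejections <- vapply(1:20, function(s) {
    set.seed(s)
    summarize_diameters(data.frame(d_um = rlnorm(5000)))$shapiro_p < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 2)
  # giant-tail populations have > 8 um axons
  pop <- generate_axon_population(4437, seed = 21)
  expect_gt(unname(summarize_diameters(pop$table)$count_above[">8um"]), 0)
  # too few rows: summary flagged, no test
  tiny <- summarize_diameters(data.frame(d_um = c(1, 2)))
  expect_true(is.na(tiny$shapiro_p))
  expect_false(is.null(tiny$test_note))
})

test_that("bilateral doubling is exact", {
  expect_equal(as.integer(total_count(4437)), 8874)
  expect_equal(as.integer(total_count(0)), 0)
  expect_equal(as.integer(total_count(3100)), 6200)
  expect_identical(attr(total_count(1), "assumption"), "bilateral symmetry")
})
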