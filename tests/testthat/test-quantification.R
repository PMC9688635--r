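test_that("the area ratio behaves as a cell count", {
  objs <- data.frame(area_px = rep(100, 10))
  expect_equal(estimate_count(objs, 100)$estimated_count, 10)
  # printed-scale arithmetic: total area of 8070 cell-equivalents
  big <- data.frame(area_px = 8070 * 100)
  expect_equal(estimate_count(big, 100)$estimated_count, 8070)
  empty <- data.frame(area_px = numeric(0))
  r <- estimate_count(empty, 50)
  expect_equal(r$estimated_count, 0)
  expect_equal(r$density, "ultra_low")
  expect_error(estimate_count(objs, 0), "positive")
})

test_that("counts are invariant to uniform area rescaling", {
  a <- data.frame(area_px = c(90, 100, 110, 400))
  for (k in c(0.5, 2, 7)) {
    expect_equal(estimate_count(data.frame(area_px = k * a$area_px), k * 100)$estimated_count,
                 estimate_count(a, 100)$estimated_count)
  }
})

test_that("noiseless scene counts match the ground truth within 2%", {
  fx <- render_class_fixture("TB", 50, seed = 61, noiseless = TRUE)
  mca <- fx$truth$totals$mean_cell_area_px
  est <- estimate_count(fx$objects, mca)
  expect_equal(est$estimated_count, 50, tolerance = 0.02)
  expect_lt(abs(est$estimated_count - 50), 1)
})

test_that("mean cell area averages single cells and excludes clusters", {
  expect_equal(mean_cell_area(data.frame(area_px = c(100, 110, 90))), 100)
  mixed <- data.frame(area_px = c(100, 105, 95, 400))
  expect_equal(mean_cell_area(mixed), 100)
  expect_error(mean_cell_area(data.frame(area_px = numeric(0))), "manual")
  # class filter drops beads before the area statistics
  withbeads <- data.frame(area_px = c(100, 100, 6, 6))
  cls <- c("TB", "TB", "bead", "bead")
  expect_equal(mean_cell_area(withbeads, classes = cls), 100)
})

test_that("measured single-cell areas match the analytic disk area", {
  fx <- render_class_fixture("TB", 20, seed = 62, noiseless = TRUE)
  px <- optics_preset("microscope_10x")$pixel_scale
  analytic <- pi * (default_diameters()["K562"] / 2 / px)^2
  expect_equal(mean_cell_area(fx$objects), unname(analytic), tolerance = 0.02)
})

test_that("transport efficiency reproduces the printed compartment pairs", {
  e1 <- transport_efficiency(95, 77)
  expect_equal(e1$efficiency_pct, 100 * 77 / 95)  # 81.05%
  expect_equal(e1$efficiency_pct + e1$loss_pct, 100)
  expect_gt(e1$efficiency_pct, 80)
  e2 <- transport_efficiency(8070, 7036)
  expect_equal(e2$efficiency_pct, 100 * 7036 / 8070, tolerance = 1e-12)  # 87.19%
  expect_lt(e2$loss_pct, 20)
  expect_equal(transport_efficiency(50, 50)$efficiency_pct, 100)
  expect_true(transport_efficiency(50, 60)$flagged)
  expect_error(transport_efficiency(0, 10), "positive")
})

test_that("chained efficiencies compose multiplicatively", {
  a <- 120; b <- 96; c <- 84
  eab <- transport_efficiency(a, b)$efficiency_pct
  ebc <- transport_efficiency(b, c)$efficiency_pct
  eac <- transport_efficiency(a, c)$efficiency_pct
  expect_equal(eab * ebc / 100, eac)
})

test_that("rendered compartment pairs keep >= 80% efficiency at <= 20% loss", {
  for (dens in c("ultra_low", "low", "medium", "high")) {
    for (s in 1:3) {
      pr <- make_compartment_pair(dens, loss_fraction = 0.15, seed = 200 + s)
      eff <- vapply(list(pr$first, pr$last), function(sp) {
        sc <- render_scene(sp)
        objs <- segment_objects(sc$image)
        d <- band_differences(objs)
        cls <- classify_objects(d)
        estimate_count(objs, mean_cell_area(objs, classes = cls))$estimated_count
      }, numeric(1))
      expect_gte(transport_efficiency(eff[1], eff[2])$efficiency_pct, 80)
    }
  }
})

test_that("density classes follow the published bounds", {
  expect_equal(classify_density(60000), "high")
  expect_equal(classify_density(40000), "medium")
  expect_equal(classify_density(20000), "low")
  expect_equal(classify_density(500), "ultra_low")
  expect_equal(classify_density(0), "ultra_low")
  # boundaries fall to the lower class
  expect_equal(classify_density(50000), "medium")
  expect_equal(classify_density(30000), "low")
  expect_equal(classify_density(1000), "low")
})

test_that("linearity verdicts match exact, noisy and degenerate series", {
  exact <- data.frame(input_cells = c(1, 2, 3, 4), estimated_count = c(1, 2, 3, 4))
  le <- linearity_check(exact)
  expect_equal(le$slope, 1)
  expect_equal(le$r_squared, 1)
  expect_equal(le$verdict, "linear")
  flat <- data.frame(input_cells = c(1, 2, 3), estimated_count = c(5, 5, 5))
  lf <- linearity_check(flat)
  expect_equal(lf$r_squared, 0)
  expect_equal(lf$verdict, "non_linear")
  expect_error(linearity_check(exact[1:2, ]), "3 points")
})
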