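test_that("an empty noiseless scene is a flat field at the background mean", {
  op <- noiseless_optics()
  sc <- render_scene(scene_spec(optics = op, seed = 1))
  expect_equal(dim(sc$image), c(512L, 512L, 3L))
  expect_true(all(sc$image == 225))
  expect_equal(nrow(sc$truth$objects), 0L)
  expect_equal(sc$truth$totals$total_object_area_px, 0)
})

test_that("noiseless disk interiors sit exactly at background minus deficit", {
  op <- noiseless_optics()
  profs <- table1_deficits()
  for (kind in rownames(profs)) {
    sc <- render_scene(scene_spec(optics = op,
                                  counts = stats::setNames(1L, kind), seed = 3))
    ob <- sc$truth$objects
    idx <- which(sc$image[, , 1] < 225, arr.ind = TRUE)
    expect_equal(nrow(idx), ob$area_px)
    for (b in 1:3) {
      vals <- sc$image[, , b][sc$image[, , 1] < 225]
      expect_true(all(vals == 225 - profs[kind, b]),
                  label = paste(kind, "band", b))
    }
  }
})

test_that("rendering is bit-identical under the same spec and seed", {
  sp <- scene_spec(counts = c(TB = 10, bead = 5), seed = 11)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- render_scene(scene_spec(counts = c(TB = 10, bead = 5), seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("ground-truth totals are exact sums over painted disks", {
  op <- noiseless_optics()
  sc <- render_scene(scene_spec(optics = op, counts = c(TB = 12, bead = 6), seed = 4))
  tr <- sc$truth
  # non-overlapping: union area equals the sum of per-object areas
  expect_equal(tr$totals$total_object_area_px, sum(tr$objects$area_px))
  is_cell <- tr$objects$kind != "bead"
  expect_equal(tr$totals$mean_cell_area_px, mean(tr$objects$area_px[is_cell]))
  # every painted pixel is accounted for
  expect_equal(sum(sc$image[, , 1] < 225), tr$totals$total_object_area_px)
})

test_that("clustered scenes merge overlapping disks in the union area", {
  op <- noiseless_optics("microscope_4x")
  sc <- render_scene(scene_spec(optics = op, counts = c(TB = 20),
                                placement = "clustered", seed = 5))
  tr <- sc$truth
  expect_lt(tr$totals$total_object_area_px, sum(tr$objects$area_px))
  expect_equal(sum(sc$image[, , 1] < 225), tr$totals$total_object_area_px)
})

test_that("overcrowded non-overlapping placement fails with a density error", {
  op <- optics_profile(image_shape = c(64L, 64L), pixel_scale = 0.65)
  expect_error(render_scene(scene_spec(optics = op, counts = c(TB = 60), seed = 1)),
               "dense")
})

test_that("unknown object kinds are rejected", {
  expect_error(scene_spec(counts = c(eosin = 3), seed = 1), "unknown stain profile")
})

test_that("default diameters encode the bead size and the K562/lymphocyte ratio", {
  d <- default_diameters()
  expect_equal(unname(d["bead"]), 4.5)
  expect_equal(unname(d["K562"] / d["lymphocyte"]), 2.5)
})

test_that("phone rendering preserves a flat field and is deterministic", {
  op <- noiseless_optics("microscope_4x")
  sc <- render_scene(scene_spec(optics = op, seed = 1))
  ph <- render_phone_view(sc$image, seed = 42)
  expect_equal(mean(ph), 225, tolerance = 0.01)
  expect_identical(ph, render_phone_view(sc$image, seed = 42))
  expect_false(identical(ph, render_phone_view(sc$image, seed = 43)))
})

test_that("phone rendering scales conjugate area by the squared pixel-scale ratio", {
  sp <- scene_spec(optics = optics_preset("microscope_4x"),
                   counts = c(TB = 40, bead = 10), placement = "clustered", seed = 3)
  sc <- render_scene(sp)
  ph <- render_phone_view(sc$image, seed = 3)
  k <- optics_preset("phone")$pixel_scale / optics_preset("microscope_4x")$pixel_scale
  # threshold at half the interior deficit: the half-rise contour tracks the
  # true object boundary, the unbiased area readout under blur
  mic <- segment_objects(sc$image, min_deficit = 20)
  pho <- segment_objects(ph, min_deficit = 20)
  expect_equal(sum(pho$area_px), sum(mic$area_px) / k^2, tolerance = 0.10)
})

test_that("phone rendering refuses a finer-than-source pixel scale", {
  sc <- render_scene(scene_spec(optics = optics_preset("microscope_4x"), seed = 1))
  fine <- optics_profile(pixel_scale = 0.5, modality = "phone")
  expect_error(render_phone_view(sc$image, fine), "coarser")
})

test_that("compartment pairs apply the loss fraction to the cell count", {
  pr <- make_compartment_pair("ultra_low", loss_fraction = 0.19, seed = 1)
  expect_equal(pr$first_cells, 95L)
  expect_equal(pr$last_cells, 77L)
  pr0 <- make_compartment_pair("low", loss_fraction = 0, seed = 1)
  expect_equal(pr0$first_cells, pr0$last_cells)
  # bead content preserved
  expect_equal(pr$first$counts[["bead"]], pr$last$counts[["bead"]])
  expect_error(make_compartment_pair("low", loss_fraction = 1), "loss_fraction")
  # scaled-down area-equivalent counts keep >= 80% for losses up to 0.2
  pr2 <- make_compartment_pair(first_count = 8070, loss_fraction = 0.2, seed = 1)
  expect_gte(pr2$last_cells, 0.8 * pr2$first_cells)
})
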