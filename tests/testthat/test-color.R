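test_that("band differences are exact unclamped subtractions", {
  expect_equal(unlist(band_differences(c(175, 185, 185), c(225, 225, 225))[, 2:4]),
               c(d_r = 50, d_g = 40, d_b = 40))
  expect_equal(unlist(band_differences(c(100, 105, 85), c(225, 225, 225))[, 2:4]),
               c(d_r = 125, d_g = 120, d_b = 140))
  expect_equal(unlist(band_differences(c(225, 225, 225), c(225, 225, 225))[, 2:4]),
               c(d_r = 0, d_g = 0, d_b = 0))
  # brighter-than-background objects give negative, unclamped values
  expect_equal(band_differences(c(230, 225, 225), c(225, 225, 225))$d_r, -5)
})

test_that("band differences are affine in the object mean", {
  bg <- c(225, 225, 225)
  base <- c(20, 30, 40)
  for (k in c(0.5, 1, 2, 3)) {
    d <- band_differences(bg - k * base, bg)
    expect_equal(unname(unlist(d[, 2:4])), k * base)
  }
})

test_that("the dominant band is the brightest (smallest-deficit) band", {
  expect_equal(dominant_band(c(25, 135, 100)), list(band = "R", tie = FALSE))
  expect_equal(dominant_band(c(100, 115, 30)), list(band = "B", tie = FALSE))
  expect_equal(dominant_band(c(100, 100, 45)), list(band = "B", tie = FALSE))
  tie <- dominant_band(c(10, 10, 10))
  expect_equal(tie$band, "R")
  expect_true(tie$tie)
})

test_that("the default rule table classifies every bundled profile correctly", {
  rule <- classification_rules()
  profs <- table1_deficits()
  for (kind in rownames(profs)) {
    expect_equal(classify_object(profs[kind, ], rule), kind)
  }
  expect_equal(classify_object(c(5, 5, 5), rule), "background")
  expect_equal(classify_object(c(15, 135, 30), rule), "unknown")
})

test_that("rule validation rejects partially overlapping intervals", {
  rule <- classification_rules()
  broken <- rule
  broken$lo[2, 1] <- rule$lo[1, 1] - 1
  broken$hi[2, 1] <- rule$hi[1, 1] - 1
  expect_error(stainsight:::validate_rules(broken), "overlapping")
})

test_that("noisy synthetic objects classify at >= 99% accuracy per class", {
  for (kind in rownames(table1_deficits())) {
    labels <- character(0)
    for (s in 1:5) {
      fx <- render_class_fixture(kind, 100, seed = 500 + s)
      labels <- c(labels, classify_objects(fx$differences))
    }
    expect_gte(length(labels), 500 * 0.98)  # near-perfect detection
    expect_gte(mean(labels == kind), 0.99)
  }
})

test_that("summaries recover class means and the stained range", {
  profs <- table1_deficits()
  stained <- c("TB", "safranin", "MB", "CV")
  d <- data.frame(d_r = profs[stained, 1], d_g = profs[stained, 2],
                  d_b = profs[stained, 3])
  sm <- summarize_differences(d, stained, allow_fewer = TRUE)
  expect_equal(unname(sm$stained_range), c(25, 135))
  expect_error(summarize_differences(d, stained), "at least 20")
  # identical objects in one class have zero spread
  d2 <- data.frame(d_r = rep(50, 25), d_g = rep(40, 25), d_b = rep(40, 25))
  sm2 <- summarize_differences(d2, rep("TB", 25))
  expect_equal(unname(unlist(sm2$per_class[1, c("sd_r", "sd_g", "sd_b")])),
               c(0, 0, 0))
  expect_equal(unname(unlist(sm2$per_class[1, c("mean_r", "mean_g", "mean_b")])),
               c(50, 40, 40))
})

test_that("relative change matches hand arithmetic and the deficit identity", {
  expect_equal(unname(relative_change(c(200, 200, 200), c(160, 180, 198))),
               c(20, 10, 1))
  expect_equal(unname(relative_change(c(180, 190, 200), c(180, 190, 200))),
               c(0, 0, 0))
  expect_error(relative_change(c(0, 200, 200), c(1, 1, 1)), "positive")
  # with the background as reference, change/100 equals d / background
  bg <- c(225, 225, 225)
  obj <- c(175, 185, 185)
  d <- unlist(band_differences(obj, bg)[, 2:4])
  expect_equal(unname(relative_change(bg, obj)) / 100, unname(d) / bg)
})

test_that("dilution series trends are detected band by band", {
  s <- data.frame(concentration_pct = c(0.1, 0.05, 0.01),
                  d_r = c(50, 35, 20), d_g = c(40, 30, 22), d_b = c(40, 36, 34))
  tr <- concentration_trend(s)
  expect_equal(tr$verdict, "monotone")
  expect_equal(tr$greatest_change_band, "R")
  flat <- data.frame(concentration_pct = c(0.1, 0.01),
                     d_r = c(30, 30), d_g = c(30, 30), d_b = c(30, 30))
  expect_equal(concentration_trend(flat)$verdict, "flat")
  # generator-backed series: strictly decreasing deficit profiles
  profs <- stain_profiles()
  dil <- c(1, 0.7, 0.4)
  rows <- lapply(seq_along(dil), function(i) {
    p <- profs
    p$TB$deficit_rgb <- round(p$TB$deficit_rgb * dil[i])
    op <- noiseless_optics()
    sc <- render_scene(scene_spec(optics = op, counts = c(TB = 10),
                                  seed = 70 + i, profiles = p))
    o <- segment_objects(sc$image)
    d <- band_differences(o)
    data.frame(concentration_pct = c(0.1, 0.05, 0.01)[i],
               d_r = mean(d$d_r), d_g = mean(d$d_g), d_b = mean(d$d_b))
  })
  tr2 <- concentration_trend(do.call(rbind, rows))
  expect_equal(unname(tr2$per_band), rep("monotone", 3))
})

test_that("phone-pair stain change ranks bands as red > green > blue", {
  m <- mobile_stain_change(seed = 1)
  expect_equal(m$largest_band, "R")
  expect_equal(m$smallest_band, "B")
  expect_gt(m$change["R"], m$change["G"])
  expect_gt(m$change["G"], m$change["B"])
})
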