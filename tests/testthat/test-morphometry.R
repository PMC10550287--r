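test_that("segmentation recovers painted shapes and picks the largest cell", {
  px <- matrix(0, 200, 200)
  px[disk_mask(200, 200, 60)] <- 100
  img <- intensity_image(px, pixel_size_um = 1)
  m <- segment_cell(img)
  expect_equal(sum(m$pixels), sum(disk_mask(200, 200, 60)), tolerance = 0.01)

  two <- matrix(0, 220, 220)
  big <- disk_mask(220, 220, 40, cy = 70, cx = 70)    # ~5027 px
  small <- disk_mask(220, 220, 12, cy = 180, cx = 180) # ~452 px
  two[big] <- 100
  two[small] <- 100
  m2 <- segment_cell(intensity_image(two, 1))
  expect_equal(sum(m2$pixels & big) / sum(big), 1, tolerance = 0.02)
  expect_false(any(m2$pixels[small]))

  expect_error(segment_cell(intensity_image(matrix(0, 64, 64), 1)),
               class = "pabscope_no_cell_found")
})

test_that("shape metrics match analytic values for canonical shapes", {
  disk <- measure_shape(cell_mask(disk_mask(256, 256, 100), 1))
  expect_equal(disk$area_um2, pi * 100^2, tolerance = 0.01)
  expect_equal(disk$circularity, 1.00, tolerance = 0.02)

  sq <- matrix(FALSE, 150, 150)
  sq[26:125, 26:125] <- TRUE
  square <- measure_shape(cell_mask(sq, 1))
  expect_equal(square$circularity, pi / 4, tolerance = 0.02 / (pi / 4))

  # 4:1 ellipse: Ramanujan perimeter gives C ~ 0.54 < 0.6
  ph <- make_cell_phantom(phantom_cell_spec("polarized", axis_ratio = 4,
                                            equivalent_radius_um = 14,
                                            seed = 1))
  ell <- measure_shape(ph$mask)
  expect_lt(ell$circularity, 0.6)
  expect_equal(ell$circularity, ellipse_circularity(14 * 2 / 0.4, 14 / 2 / 0.4),
               tolerance = 0.03)

  expect_error(measure_shape(cell_mask(matrix(FALSE, 10, 10), 1)),
               class = "pabscope_validation_error")
})

test_that("border band depth follows the annulus area law", {
  mask <- cell_mask(disk_mask(256, 256, 100), 1)
  band <- border_band(mask, 0.15)
  ratio <- sum(band$pixels) / sum(mask$pixels)
  expect_equal(ratio, 1 - 0.85^2, tolerance = 0.01 / (1 - 0.85^2))
  expect_true(all(mask$pixels[band$pixels]))  # band subset of mask

  expect_identical(border_band(mask, 1)$pixels, mask$pixels)
  expect_error(border_band(mask, 0), class = "pabscope_validation_error")
})

test_that("border actin fraction integrates background-subtracted intensity", {
  m <- disk_mask(128, 128, 50)
  mask <- cell_mask(m, 1)
  band <- border_band(mask, 0.2)

  ring_only <- matrix(0, 128, 128)
  ring_only[band$pixels] <- 40
  expect_equal(
    border_actin_fraction(intensity_image(ring_only, 1), mask, band,
                          background = 0), 1.0)

  uniform <- matrix(0, 128, 128)
  uniform[m] <- 70
  f_unif <- border_actin_fraction(intensity_image(uniform, 1), mask, band,
                                  background = 0)
  expect_equal(f_unif, sum(band$pixels) / sum(m), tolerance = 1e-12)

  # invariance to multiplicative rescaling (background from outside median)
  base <- uniform + 10
  f1 <- border_actin_fraction(intensity_image(base, 1), mask, band)
  f3 <- border_actin_fraction(intensity_image(base * 3, 1), mask, band)
  expect_equal(f1, f3, tolerance = 1e-12)

  expect_error(
    border_actin_fraction(intensity_image(matrix(0, 128, 128), 1), mask, band),
    class = "pabscope_undefined_fraction")
})

test_that("PAB decision rule uses strict inequalities on both metrics", {
  expect_true(classify_pab(0.60, 0.80))
  expect_false(classify_pab(0.40, 0.90))
  expect_false(classify_pab(0.50, 0.60))
  expect_false(classify_pab(0.50, 0.95))
  expect_false(classify_pab(0.95, 0.60))
  expect_true(classify_pab(0.50 + 1e-9, 0.60 + 1e-9))
})

test_that("pab_rate aggregates per field", {
  recs <- tibble::tibble(
    field_id = rep(c("f1", "f2"), c(10, 4)),
    is_pab = c(rep(c(TRUE, FALSE), c(2, 8)), rep(TRUE, 4))
  )
  out <- pab_rate(recs)
  expect_equal(out$pab_percent[out$field_id == "f1"], 20)
  expect_equal(out$pab_percent[out$field_id == "f2"], 100)
  expect_error(pab_rate(recs[0, ]), class = "pabscope_validation_error")
})

test_that("focal adhesion detection counts resolvable puncta", {
  blank <- intensity_image(matrix(1, 128, 128), 0.2)
  expect_equal(nrow(detect_focal_adhesions(blank)), 0)

  centers <- cbind(c(30, 30, 64, 100, 100), c(30, 100, 64, 30, 100))
  five <- matrix(0, 128, 128)
  for (i in 1:5) {
    five <- five + 100 * exp(-((row(five) - centers[i, 1])^2 +
                               (col(five) - centers[i, 2])^2) / (2 * 2^2))
  }
  fa <- detect_focal_adhesions(intensity_image(five, 0.2),
                               size_range_um2 = c(0.05, 50))
  expect_equal(nrow(fa), 5)

  merged <- matrix(0, 128, 128)
  for (cc in c(62, 66)) {
    merged <- merged + 100 * exp(-((row(merged) - 64)^2 +
                                   (col(merged) - cc)^2) / (2 * 2^2))
  }
  fa2 <- detect_focal_adhesions(intensity_image(merged, 0.2),
                                size_range_um2 = c(0.05, 50))
  expect_equal(nrow(fa2), 1)
})

test_that("shape metrics are stable under resampling and rotation", {
  # same physical cell rendered at two pixel sizes
  hi <- make_cell_phantom(phantom_cell_spec("polarized", axis_ratio = 2,
                                            pixel_size_um = 0.2,
                                            image_size_px = c(384, 384),
                                            seed = 2))
  lo <- make_cell_phantom(phantom_cell_spec("polarized", axis_ratio = 2,
                                            pixel_size_um = 0.4,
                                            image_size_px = c(192, 192),
                                            seed = 2))
  s_hi <- measure_shape(hi$mask)
  s_lo <- measure_shape(lo$mask)
  expect_equal(s_hi$area_um2, s_lo$area_um2, tolerance = 0.02)
  expect_equal(s_hi$perimeter_um, s_lo$perimeter_um, tolerance = 0.02)
  expect_lt(abs(s_hi$circularity - s_lo$circularity), 0.02)

  circs <- sapply(c(0, 30, 60, 90) * pi / 180, function(th) {
    ph <- make_cell_phantom(phantom_cell_spec("polarized", axis_ratio = 2,
                                              orientation_rad = th, seed = 2))
    measure_shape(ph$mask)$circularity
  })
  expect_lt(diff(range(circs)), 0.02)
})

test_that("measured border fraction increases with the phantom ring share", {
  shares <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  measured <- sapply(shares, function(s) {
    ph <- make_cell_phantom(phantom_cell_spec("pab", ring_intensity_share = s,
                                              seed = 5))
    measure_cell(ph$image)$border_fraction
  })
  expect_true(all(diff(measured) > 0))
})
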