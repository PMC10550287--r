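test_that("phantom generation is deterministic and honors its ground truth", {
  spec <- phantom_cell_spec("pab", ring_intensity_share = 0.80,
                            noise_sd = 5, seed = 11)
  a <- make_cell_phantom(spec)
  b <- make_cell_phantom(spec)
  expect_identical(a$image$pixels, b$image$pixels)

  noiseless <- make_cell_phantom(
    phantom_cell_spec("pab", ring_intensity_share = 0.80, noise_sd = 0,
                      seed = 11))
  expect_true(all(noiseless$image$pixels >= 0))
  expect_equal(noiseless$border_fraction, 0.80, tolerance = 0.02 / 0.80)
  # mask is one connected component
  lab <- EBImage::bwlabel(noiseless$mask$pixels)
  expect_equal(max(lab), 1)
})

test_that("pab phantoms classify true, strongly polarized phantoms false", {
  pab <- make_cell_phantom(phantom_cell_spec("pab",
                                             ring_intensity_share = 0.80,
                                             seed = 3))
  rec <- measure_cell(pab$image)
  expect_true(rec$is_pab)

  pol <- make_cell_phantom(phantom_cell_spec("polarized", axis_ratio = 4,
                                             equivalent_radius_um = 14,
                                             seed = 4))
  rec2 <- measure_cell(pol$image)
  expect_lt(rec2$circularity, 0.6)
  expect_false(rec2$is_pab)
})

test_that("phantom geometry and parameter validation reject bad specs", {
  expect_error(
    make_cell_phantom(phantom_cell_spec("pab", equivalent_radius_um = 60,
                                        image_size_px = c(128, 128))),
    class = "pabscope_geometry_error")
  expect_error(phantom_cell_spec("pab", pixel_size_um = 0),
               class = "pabscope_validation_error")
  expect_error(phantom_cell_spec("pab", axis_ratio = 2),
               class = "pabscope_validation_error")
})

test_that("traction scenes obey linearity and force balance", {
  spots0 <- tibble::tibble(cx_um = c(40, 88), cy_um = 64,
                           amplitude_pa = c(0, 0), sigma_um = 4,
                           dir_x = c(1, -1), dir_y = 0)
  zero <- make_traction_scene(traction_scene_spec(spots = spots0))
  expect_equal(max(abs(zero$displacement$ux)), 0)
  expect_equal(max(abs(zero$displacement$uy)), 0)

  sc1 <- two_spot_scene()
  spots2 <- traction_scene_spec()$spots
  spots2$amplitude_pa <- spots2$amplitude_pa * 2
  sc2 <- make_traction_scene(traction_scene_spec(spots = spots2))
  expect_equal(sc2$displacement$ux, 2 * sc1$displacement$ux, tolerance = 1e-12)
  expect_equal(sc2$displacement$uy, 2 * sc1$displacement$uy, tolerance = 1e-12)

  # force balance of the rendered field
  tot <- sum(abs(sc1$traction$tx)) + sum(abs(sc1$traction$ty))
  expect_lt(abs(sum(sc1$traction$tx)) + abs(sum(sc1$traction$ty)), 1e-9 * tot)

  bad <- tibble::tibble(cx_um = 40, cy_um = 64, amplitude_pa = 100,
                        sigma_um = 4, dir_x = 1, dir_y = 0)
  expect_error(traction_scene_spec(spots = bad),
               class = "pabscope_validation_error")
})

test_that("two-spot displacement peaks between the spots and decays outward", {
  sc <- two_spot_scene()
  mag <- sqrt(sc$displacement$ux^2 + sc$displacement$uy^2)
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  h <- 1  # 0.5 um/px * 2 px spacing
  x_pk <- (unname(pk[2]) - 0.5) * h
  y_pk <- (unname(pk[1]) - 0.5) * h
  # spots sit at x = 46 and 82 um, y = 64 um
  expect_gt(x_pk, 36)
  expect_lt(x_pk, 92)
  expect_lt(abs(y_pk - 64), 1)
  expect_lt(mag[1, 1], 0.05 * max(mag))
})

test_that("bead rendering respects the displacement field", {
  zero <- displacement_field(matrix(0, 32, 32), matrix(0, 32, 32),
                             grid_spacing_px = 8, pixel_size_um = 0.5)
  bi <- render_bead_images(zero, n_beads = 200, seed = 2)
  expect_identical(bi$reference$pixels, bi$deformed$pixels)
  expect_equal(nrow(bi$beads), 200)

  uni <- displacement_field(matrix(3 * 0.5, 32, 32), matrix(-2 * 0.5, 32, 32),
                            grid_spacing_px = 8, pixel_size_um = 0.5)
  bu <- render_bead_images(uni, n_beads = 300, seed = 7)
  reg <- register_reference(bu$reference, bu$deformed)
  expect_equal(unname(reg$shift_px), c(-2, 3), tolerance = 0.1 / 2)

  expect_error(render_bead_images(zero, n_beads = 0),
               class = "pabscope_validation_error")
})

test_that("simulated tracks hit the specified speed and persistence limits", {
  ballistic <- make_tracks(track_sim_spec(n_tracks = 5, persistence = 1,
                                          n_steps = 20, seed = 9))
  st <- track_stats(ballistic)
  expect_equal(st$directionality, rep(1, 5), tolerance = 1e-12)

  spec <- track_sim_spec(n_tracks = 1000, mean_speed_um_min = 0.5,
                         persistence = 0.5, n_steps = 30, seed = 21)
  st2 <- track_stats(make_tracks(spec))
  se <- sd(st2$mean_speed_um_min) / sqrt(nrow(st2))
  expect_lt(abs(mean(st2$mean_speed_um_min) - 0.5), 3 * se)

  expect_identical(make_tracks(spec), make_tracks(spec))
})

test_that("synthetic force curves are reproducible with flat pre-contact", {
  fc <- make_force_curve(E_pa = 8000, z0_um = 1.5, z_range_um = c(0, 3),
                         noise_sd_n = 1e-11, seed = 5)
  fc2 <- make_force_curve(E_pa = 8000, z0_um = 1.5, z_range_um = c(0, 3),
                          noise_sd_n = 1e-11, seed = 5)
  expect_identical(fc$d_um, fc2$d_um)

  flat <- make_force_curve(E_pa = 8000, z0_um = 10, z_range_um = c(0, 3))
  expect_true(all(flat$d_um == 0))
})

test_that("calcium traces normalize to first frame and scale out baseline", {
  tr <- make_calcium_trace(baseline = 50, peak_fold = 2, onset_frame = 5,
                           n_frames = 25)
  fc <- fold_change_trace(tr)
  expect_equal(fc$fold_change[1], 1)
  expect_equal(max(fc$fold_change), 2)

  tr10 <- make_calcium_trace(baseline = 500, peak_fold = 2, onset_frame = 5,
                             n_frames = 25)
  expect_equal(fold_change_trace(tr10)$fold_change, fc$fold_change)

  expect_error(make_calcium_trace(onset_frame = 30, n_frames = 25),
               class = "pabscope_validation_error")
})
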