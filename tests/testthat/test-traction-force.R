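test_that("forward Boussinesq solution is linear in traction and compliance", {
  sc <- two_spot_scene()
  zero <- traction_field(matrix(0, 128, 128), matrix(0, 128, 128),
                         grid_spacing_px = 2, pixel_size_um = 0.5)
  u0 <- forward_displacement(zero, sc$substrate)
  expect_equal(max(abs(u0$ux)), 0)

  t2 <- sc$traction
  t2$tx <- 2 * t2$tx
  t2$ty <- 2 * t2$ty
  u2 <- forward_displacement(t2, sc$substrate)
  expect_equal(u2$ux, 2 * sc$displacement$ux, tolerance = 1e-12)

  soft <- substrate_model(youngs_modulus_pa = sc$substrate$E / 2,
                          poisson_ratio = sc$substrate$nu)
  u_soft <- forward_displacement(sc$traction, soft)
  expect_equal(u_soft$ux, 2 * sc$displacement$ux, tolerance = 1e-12)
  expect_equal(u_soft$uy, 2 * sc$displacement$uy, tolerance = 1e-12)

  unbal <- traction_field(matrix(1, 32, 32), matrix(0, 32, 32))
  expect_error(forward_displacement(unbal, sc$substrate),
               class = "pabscope_validation_error")
})

test_that("unregularized FTTC inverts the forward model", {
  sc <- two_spot_scene()
  t_hat <- fttc(sc$displacement, sc$substrate, lambda = 0)
  expect_lt(rel_l2(t_hat$tx, t_hat$ty, sc$traction$tx, sc$traction$ty), 0.05)

  zero_u <- displacement_field(matrix(0, 32, 32), matrix(0, 32, 32))
  t0 <- fttc(zero_u, sc$substrate, lambda = 0)
  expect_equal(max(abs(t0$tx)), 0)

  small <- displacement_field(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(fttc(small, sc$substrate), class = "pabscope_validation_error")
})

test_that("Tikhonov regularization shrinks the traction monotonically", {
  sc <- two_spot_scene(noise_sd_um = 0.003)
  u <- sc$displacement_noisy
  lams <- c(0, 1e-10, 1e-9, 1e-8, 1e-7)
  norms <- sapply(lams, function(l) {
    t_hat <- fttc(u, sc$substrate, lambda = l)
    sqrt(sum(t_hat$tx^2 + t_hat$ty^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("FTTC is equivariant under whole-node translations", {
  sc <- two_spot_scene()
  roll <- function(m, k) {
    m[c((k + 1):nrow(m), 1:k), , drop = FALSE]
  }
  u_roll <- displacement_field(roll(sc$displacement$ux, 10),
                               roll(sc$displacement$uy, 10),
                               sc$displacement$grid_spacing_px,
                               sc$displacement$pixel_size_um)
  t_roll <- fttc(u_roll, sc$substrate, lambda = 0)
  t_ref <- fttc(sc$displacement, sc$substrate, lambda = 0)
  expect_equal(t_roll$tx, roll(t_ref$tx, 10), tolerance = 1e-9)
})

test_that("traction inversion is unchanged by equivalent pixel/grid geometry", {
  sc <- two_spot_scene()  # pixel 0.5 um, spacing 2 px -> h = 1 um
  u_alt <- displacement_field(sc$displacement$ux, sc$displacement$uy,
                              grid_spacing_px = 1, pixel_size_um = 1)
  t1 <- fttc(sc$displacement, sc$substrate, lambda = 0)
  t2 <- fttc(u_alt, sc$substrate, lambda = 0)
  expect_equal(t1$tx, t2$tx, tolerance = 1e-12)
})

test_that("registration recovers rigid shifts and rejects incoherent pairs", {
  f <- displacement_field(matrix(0, 32, 32), matrix(0, 32, 32),
                          grid_spacing_px = 8, pixel_size_um = 0.5)
  bi <- render_bead_images(f, n_beads = 300, seed = 13)

  same <- register_reference(bi$reference, bi$reference)
  expect_equal(unname(same$shift_px), c(0, 0), tolerance = 1e-6)

  shifted <- intensity_image(
    pmax(pabscope:::fourier_shift(bi$reference$pixels, 7, -3), 0), 0.5)
  reg <- register_reference(bi$reference, shifted)
  expect_equal(unname(reg$shift_px), c(7, -3), tolerance = 0.1)

  set.seed(4)
  n1 <- intensity_image(matrix(runif(128^2), 128), 0.5)
  n2 <- intensity_image(matrix(runif(128^2), 128), 0.5)
  expect_error(register_reference(n1, n2),
               class = "pabscope_registration_failed")
})

test_that("windowed flow recovers uniform and smooth displacement fields", {
  still <- displacement_field(matrix(0, 32, 32), matrix(0, 32, 32),
                              grid_spacing_px = 8, pixel_size_um = 0.5)
  bi <- render_bead_images(still, n_beads = 400, seed = 3)
  d0 <- estimate_displacements(bi$reference, bi$deformed, window_px = 16,
                               grid_spacing_px = 8, search_px = 4)
  expect_lt(max(abs(c(d0$ux, d0$uy))) / 0.5, 0.05)  # < 0.05 px

  uni <- displacement_field(matrix(1.5, 32, 32), matrix(-1.0, 32, 32),
                            grid_spacing_px = 8, pixel_size_um = 0.5)
  bu <- render_bead_images(uni, n_beads = 400, seed = 5)
  du <- estimate_displacements(bu$reference, bu$deformed, window_px = 16,
                               grid_spacing_px = 8, search_px = 6)
  expect_equal(mean(du$ux) / 0.5, 3.0, tolerance = 0.1 / 3)
  expect_equal(mean(du$uy) / 0.5, -2.0, tolerance = 0.1 / 2)

  # smooth field round trip at 5% image noise
  spots <- tibble::tibble(cx_um = c(40, 88), cy_um = 64,
                          amplitude_pa = 500, sigma_um = 12,
                          dir_x = c(1, -1), dir_y = 0)
  sc <- make_traction_scene(traction_scene_spec(
    grid_size = c(32, 32), pixel_size_um = 0.5, grid_spacing_px = 8,
    substrate = substrate_model(shear_modulus_pa = 2000), spots = spots))
  # ~5 beads per 16 px window (PIV seeding practice) on the 256 px field
  bs <- render_bead_images(sc$displacement, n_beads = 1200,
                           psf_sigma_px = 1.5, noise_sd = 0.05, seed = 11)
  ds <- estimate_displacements(bs$reference, bs$deformed, window_px = 16,
                               grid_spacing_px = 8, search_px = 6)
  truth <- pabscope:::interp_field_at(
    sc$displacement,
    as.vector((row(ds$ux) - 0.5) * ds$grid_spacing_px + ds$origin_px[1]),
    as.vector((col(ds$ux) - 0.5) * ds$grid_spacing_px + ds$origin_px[2]))
  r <- stats::cor(c(ds$ux, ds$uy), c(truth$ux, truth$uy))
  expect_gt(r, 0.95)
})

test_that("strain energy arithmetic and bilinearity are exact", {
  u1 <- displacement_field(matrix(1, 1, 1), matrix(0, 1, 1),
                           grid_spacing_px = 1, pixel_size_um = 1)
  t1 <- traction_field(matrix(100, 1, 1), matrix(0, 1, 1),
                       grid_spacing_px = 1, pixel_size_um = 1)
  res <- strain_energy(u1, t1, matrix(TRUE, 1, 1))
  expect_equal(res$strain_energy_j, 5e-17)
  expect_equal(res$normalized_energy_j_per_um2, 5e-17)

  sc <- two_spot_scene()
  mask <- two_spot_mask(sc)
  base <- strain_energy(sc$displacement, sc$traction, mask)
  u2 <- sc$displacement
  u2$ux <- 2 * u2$ux
  u2$uy <- 2 * u2$uy
  t2 <- sc$traction
  t2$tx <- 2 * t2$tx
  t2$ty <- 2 * t2$ty
  quad <- strain_energy(u2, t2, mask)
  expect_equal(quad$strain_energy_j, 4 * base$strain_energy_j,
               tolerance = 1e-12)

  zero_t <- traction_field(matrix(0, 128, 128), matrix(0, 128, 128),
                           2, 0.5)
  expect_equal(strain_energy(sc$displacement, zero_t, mask)$strain_energy_j, 0)
  expect_error(strain_energy(sc$displacement, sc$traction,
                             matrix(FALSE, 128, 128)),
               class = "pabscope_validation_error")
})

test_that("substrate strain energy is non-negative for any balanced traction", {
  substrate <- substrate_model(shear_modulus_pa = 16000)
  for (seed in 1:5) {
    set.seed(seed)
    tx <- matrix(rnorm(64 * 64), 64, 64)
    ty <- matrix(rnorm(64 * 64), 64, 64)
    sm <- pabscope:::gaussian_blur(tx, 3)
    sm2 <- pabscope:::gaussian_blur(ty, 3)
    tr <- traction_field(100 * (sm - mean(sm)), 100 * (sm2 - mean(sm2)))
    u <- forward_displacement(tr, substrate)
    res <- strain_energy(u, tr, NULL)
    expect_gte(res$strain_energy_j, 0)
  }
})

test_that("residual energy fraction splits energy by the cell footprint", {
  sc <- two_spot_scene()
  inside <- two_spot_mask(sc)
  qc <- residual_energy_fraction(sc$displacement, sc$traction, inside,
                                 margin_px = 10)
  expect_lt(qc$residual_energy_fraction, 0.05)
  expect_true(qc$passed_qc)

  # mask covering only the left spot of the symmetric dipole: half in, half out
  nr <- nrow(sc$traction$tx)
  left <- matrix(FALSE, nr, nr)
  left[, 1:(nr / 2)] <- TRUE
  qc_half <- residual_energy_fraction(sc$displacement, sc$traction, left,
                                      margin_px = 0)
  expect_equal(qc_half$residual_energy_fraction, 0.5, tolerance = 0.02)
  expect_false(qc_half$passed_qc)

  zero_t <- traction_field(matrix(0, 128, 128), matrix(0, 128, 128), 2, 0.5)
  expect_error(residual_energy_fraction(sc$displacement, zero_t, inside),
               class = "pabscope_undefined_fraction")
})

test_that("the QC threshold excludes at exactly 20% residual energy", {
  # point-energy construction: 4 units inside the mask, 1 unit outside
  # -> fraction exactly 0.2 (excluded); 81/19 split -> 0.19 (retained)
  build <- function(e_in, e_out) {
    ux <- matrix(0, 32, 32)
    tx <- matrix(0, 32, 32)
    ux[16, 16] <- 1
    tx[16, 16] <- e_in
    ux[16, 30] <- 1
    tx[16, 30] <- e_out
    u <- displacement_field(ux, matrix(0, 32, 32))
    tr <- traction_field(tx, matrix(0, 32, 32))
    mask <- matrix(FALSE, 32, 32)
    mask[10:22, 10:22] <- TRUE
    residual_energy_fraction(u, tr, mask, margin_px = 0)
  }
  at20 <- build(80, 20)
  expect_equal(at20$residual_energy_fraction, 0.20)
  expect_false(at20$passed_qc)
  at19 <- build(81, 19)
  expect_equal(at19$residual_energy_fraction, 0.19)
  expect_true(at19$passed_qc)
})
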