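#' Specification of a synthetic traction scene
#'
#' A traction scene is a set of Gaussian traction spots on a regular grid
#' over an elastic substrate. Spot amplitudes and directions must balance so
#' the total in-plane force is zero (a cell cannot exert net force on its
#' substrate). The default is the standard contractile two-spot dipole used
#' throughout the validation suite: two opposing 300 Pa spots pulling toward
#' each other on a 16 kPa (shear) substrate.
#'
#' @param grid_size Length-2 integer, field nodes (rows, cols).
#' @param pixel_size_um Image pixel size (um).
#' @param grid_spacing_px Node spacing in pixels.
#' @param substrate A [substrate_model()].
#' @param spots Tibble with columns `cx_um`, `cy_um`, `amplitude_pa`,
#'   `sigma_um`, `dir_x`, `dir_y` (direction need not be unit length; it is
#'   normalized).
#' @param noise_sd_um Gaussian displacement noise sd (um) per component.
#' @param seed Integer seed.
#'
#' @return A `traction_scene_spec` list.
#' @export
traction_scene_spec <- function(grid_size = c(128L, 128L),
                                pixel_size_um = 0.5,
                                grid_spacing_px = 2L,
                                substrate = substrate_model(shear_modulus_pa = 16000),
                                spots = NULL,
                                noise_sd_um = 0,
                                seed = 1L) {
  stopifnot(length(grid_size) == 2L, all(grid_size >= 16))
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  grid_spacing_px <- check_count(grid_spacing_px, "grid_spacing_px")
  stopifnot(inherits(substrate, "substrate_model"))
  h <- pixel_size_um * grid_spacing_px
  extent <- grid_size * h
  if (is.null(spots)) {
    spots <- tibble(
      cx_um = c(0.36, 0.64) * extent[2],
      cy_um = c(0.5, 0.5) * extent[1],
      amplitude_pa = c(300, 300),
      sigma_um = c(4, 4),
      dir_x = c(1, -1),
      dir_y = c(0, 0)
    )
  }
  need <- c("cx_um", "cy_um", "amplitude_pa", "sigma_um", "dir_x", "dir_y")
  stopifnot(is.data.frame(spots), all(need %in% names(spots)))
  if (any(spots$sigma_um <= pixel_size_um)) {
    abort("Spot sigma must exceed the pixel size.",
          class = "pabscope_validation_error")
  }
  # normalize directions, then check analytic force balance
  nrm <- sqrt(spots$dir_x^2 + spots$dir_y^2)
  nrm[nrm == 0] <- 1
  spots$dir_x <- spots$dir_x / nrm
  spots$dir_y <- spots$dir_y / nrm
  fx <- sum(spots$amplitude_pa * spots$sigma_um^2 * spots$dir_x)
  fy <- sum(spots$amplitude_pa * spots$sigma_um^2 * spots$dir_y)
  tot <- sum(abs(spots$amplitude_pa) * spots$sigma_um^2)
  if (tot > 0 && sqrt(fx^2 + fy^2) > 1e-6 * tot) {
    abort("Spot amplitudes do not balance: net in-plane force must be zero.",
          class = "pabscope_validation_error")
  }
  check_nonneg_scalar(noise_sd_um, "noise_sd_um")
  structure(
    list(grid_size = as.integer(grid_size), pixel_size_um = pixel_size_um,
         grid_spacing_px = grid_spacing_px, substrate = substrate,
         spots = spots, noise_sd_um = noise_sd_um, seed = as.integer(seed)),
    class = "traction_scene_spec"
  )
}

#' Generate a traction scene with ground truth
#'
#' Renders the spot tractions on the grid, zeroes the (already near-zero)
#' DC component exactly, computes the noiseless forward displacement via
#' [forward_displacement()], and adds iid Gaussian noise per component.
#'
#' @param spec A [traction_scene_spec()].
#'
#' @return List: `traction` (ground-truth [traction_field()]),
#'   `displacement` (noiseless), `displacement_noisy`, `substrate`, `spec`.
#' @export
make_traction_scene <- function(spec) {
  stopifnot(inherits(spec, "traction_scene_spec"))
  nr <- spec$grid_size[1]
  nc <- spec$grid_size[2]
  h <- spec$pixel_size_um * spec$grid_spacing_px
  x <- matrix((seq_len(nc) - 0.5) * h, nr, nc, byrow = TRUE)
  y <- matrix((seq_len(nr) - 0.5) * h, nr, nc)
  tx <- matrix(0, nr, nc)
  ty <- matrix(0, nr, nc)
  for (i in seq_len(nrow(spec$spots))) {
    s <- spec$spots[i, ]
    g <- s$amplitude_pa *
      exp(-((x - s$cx_um)^2 + (y - s$cy_um)^2) / (2 * s$sigma_um^2))
    tx <- tx + g * s$dir_x
    ty <- ty + g * s$dir_y
  }
  tx <- tx - mean(tx)
  ty <- ty - mean(ty)
  traction <- traction_field(tx, ty, spec$grid_spacing_px, spec$pixel_size_um)
  u <- forward_displacement(traction, spec$substrate)
  u_noisy <- u
  if (spec$noise_sd_um > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(derive_seed(spec$seed, 1))
    u_noisy$ux <- u$ux + matrix(rnorm(nr * nc, sd = spec$noise_sd_um), nr, nc)
    u_noisy$uy <- u$uy + matrix(rnorm(nr * nc, sd = spec$noise_sd_um), nr, nc)
  }
  list(traction = traction, displacement = u, displacement_noisy = u_noisy,
       substrate = spec$substrate, spec = spec)
}

#' Render reference / deformed bead image pairs
#'
#' Draws `n_beads` sub-diffraction beads as Gaussian point-spread spots on a
#' dark background. In the deformed image each bead sits at its reference
#' position plus the displacement bilinearly interpolated from the field at
#' the bead center — a stand-in for imaging substrate-embedded fluorescent
#' beads before and after cell attachment.
#'
#' @param field A [displacement_field()].
#' @param n_beads Number of beads (> 0).
#' @param psf_sigma_px PSF sigma in pixels.
#' @param noise_sd Gaussian image noise sd (AU; bead peak is 1).
#' @param seed Integer seed.
#'
#' @return List: `reference`, `deformed` ([intensity_image()]s), and
#'   `beads` (tibble of reference-frame bead centers in px).
#' @export
render_bead_images <- function(field, n_beads = 500L, psf_sigma_px = 1.5,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(field, "displacement_field"))
  n_beads <- check_count(n_beads, "n_beads")
  check_positive_scalar(psf_sigma_px, "psf_sigma_px")
  check_nonneg_scalar(noise_sd, "noise_sd")
  nr_px <- nrow(field$ux) * field$grid_spacing_px
  nc_px <- ncol(field$ux) * field$grid_spacing_px

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, 2))
  margin <- 4 * psf_sigma_px
  brow <- runif(n_beads, 1 + margin, nr_px - margin)
  bcol <- runif(n_beads, 1 + margin, nc_px - margin)

  u <- interp_field_at(field, brow, bcol)  # um
  drow <- brow + u$uy / field$pixel_size_um
  dcol <- bcol + u$ux / field$pixel_size_um

  ref <- render_gaussian_spots(nr_px, nc_px, brow, bcol, psf_sigma_px)
  def <- render_gaussian_spots(nr_px, nc_px, drow, dcol, psf_sigma_px)
  if (noise_sd > 0) {
    ref <- ref + matrix(rnorm(nr_px * nc_px, sd = noise_sd), nr_px, nc_px)
    def <- def + matrix(rnorm(nr_px * nc_px, sd = noise_sd), nr_px, nc_px)
  }
  list(
    reference = intensity_image(pmax(ref, 0), field$pixel_size_um, "beads"),
    deformed = intensity_image(pmax(def, 0), field$pixel_size_um, "beads"),
    beads = tibble(row_px = brow, col_px = bcol,
                   ux_um = u$ux, uy_um = u$uy)
  )
}

# Bilinear interpolation of a displacement field at pixel coordinates.
# Node (i, j) sits at pixel ((i - 0.5) * gs, (j - 0.5) * gs).
interp_field_at <- function(field, row_px, col_px) {
  gs <- field$grid_spacing_px
  gi <- row_px / gs + 0.5
  gj <- col_px / gs + 0.5
  list(ux = bilinear(field$ux, gi, gj), uy = bilinear(field$uy, gi, gj))
}

bilinear <- function(m, i, j) {
  nr <- nrow(m)
  nc <- ncol(m)
  i <- pmin(pmax(i, 1), nr)
  j <- pmin(pmax(j, 1), nc)
  i0 <- pmin(floor(i), nr - 1)
  j0 <- pmin(floor(j), nc - 1)
  fi <- i - i0
  fj <- j - j0
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

# Sum of unit-amplitude Gaussian spots at continuous (row, col) centers.
render_gaussian_spots <- function(nr, nc, rows, cols, sigma, amplitude = 1) {
  img <- matrix(0, nr, nc)
  r <- ceiling(4 * sigma)
  for (b in seq_along(rows)) {
    i0 <- max(1L, floor(rows[b] - r))
    i1 <- min(nr, ceiling(rows[b] + r))
    j0 <- max(1L, floor(cols[b] - r))
    j1 <- min(nc, ceiling(cols[b] + r))
    ii <- i0:i1
    jj <- j0:j1
    gi <- exp(-(ii - rows[b])^2 / (2 * sigma^2))
    gj <- exp(-(jj - cols[b])^2 / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gi, gj)
  }
  img
}
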