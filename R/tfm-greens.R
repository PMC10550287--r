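#' Elastic substrate model
#'
#' Supply exactly one of Young's modulus `E` or shear modulus `G`
#' (`E = 2 G (1 + nu)`). The default polyacrylamide gel has shear modulus
#' 16 kPa; with the near-incompressible default `nu = 0.5` that is
#' `E = 48 kPa`.
#'
#' @param youngs_modulus_pa Young's modulus (Pa), or `NULL`.
#' @param shear_modulus_pa Shear modulus (Pa), or `NULL`.
#' @param poisson_ratio Poisson's ratio in \[0, 0.5\].
#'
#' @return A `substrate_model` list with `E`, `nu`, `G`.
#' @export
#' @examples
#' substrate_model(shear_modulus_pa = 16000)
substrate_model <- function(youngs_modulus_pa = NULL, shear_modulus_pa = NULL,
                            poisson_ratio = 0.5) {
  if (is.null(youngs_modulus_pa) == is.null(shear_modulus_pa)) {
    abort("Supply exactly one of `youngs_modulus_pa` or `shear_modulus_pa`.",
          class = "pabscope_validation_error")
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort("`poisson_ratio` must lie in [0, 0.5].",
          class = "pabscope_validation_error")
  }
  if (is.null(youngs_modulus_pa)) {
    check_positive_scalar(shear_modulus_pa, "shear_modulus_pa")
    youngs_modulus_pa <- 2 * shear_modulus_pa * (1 + poisson_ratio)
  } else {
    check_positive_scalar(youngs_modulus_pa, "youngs_modulus_pa")
    shear_modulus_pa <- youngs_modulus_pa / (2 * (1 + poisson_ratio))
  }
  structure(
    list(E = youngs_modulus_pa, nu = poisson_ratio, G = shear_modulus_pa),
    class = "substrate_model"
  )
}

#' Regular-grid 2D vector fields
#'
#' `displacement_field()` holds bead displacements in micrometres;
#' `traction_field()` holds surface stresses in pascals on the same grid.
#' Components are matrices (`x` = columns, `y` = rows); nodes are spaced
#' `grid_spacing_px` image pixels apart, each pixel `pixel_size_um` wide.
#'
#' @param ux,uy Displacement components (um), matrices of equal size.
#' @param grid_spacing_px Node spacing in image pixels.
#' @param pixel_size_um Image pixel size (um).
#' @param origin_px Length-2 pixel offset of node (1,1).
#'
#' @return A `displacement_field` / `traction_field` object.
#' @export
displacement_field <- function(ux, uy, grid_spacing_px = 1L,
                               pixel_size_um = 1, origin_px = c(0, 0)) {
  check_field_components(ux, uy)
  check_positive_scalar(grid_spacing_px, "grid_spacing_px")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(
    list(ux = ux, uy = uy, grid_spacing_px = grid_spacing_px,
         pixel_size_um = pixel_size_um, origin_px = origin_px),
    class = "displacement_field"
  )
}

#' @rdname displacement_field
#' @param tx,ty Traction components (Pa).
#' @param lambda_used Regularization parameter used to obtain the field.
#' @param lambda_convention Units convention string recorded with `lambda`.
#' @export
traction_field <- function(tx, ty, grid_spacing_px = 1L, pixel_size_um = 1,
                           origin_px = c(0, 0), lambda_used = 0,
                           lambda_convention = "u_um_T_pa_k_rad_per_um") {
  check_field_components(tx, ty)
  check_positive_scalar(grid_spacing_px, "grid_spacing_px")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(
    list(tx = tx, ty = ty, grid_spacing_px = grid_spacing_px,
         pixel_size_um = pixel_size_um, origin_px = origin_px,
         lambda_used = lambda_used, lambda_convention = lambda_convention),
    class = "traction_field"
  )
}

check_field_components <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)) ||
      anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Field components must be equal-size finite matrices.",
          class = "pabscope_validation_error")
  }
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d nodes, spacing %g px x %g um/px, max |u| = %.4g um\n",
              nrow(x$ux), ncol(x$ux), x$grid_spacing_px, x$pixel_size_um,
              max(sqrt(x$ux^2 + x$uy^2))))
  invisible(x)
}

#' @export
print.traction_field <- function(x, ...) {
  cat(sprintf("<traction_field> %d x %d nodes, max |T| = %.4g Pa, lambda = %g (%s)\n",
              nrow(x$tx), ncol(x$tx), max(sqrt(x$tx^2 + x$ty^2)),
              x$lambda_used, x$lambda_convention))
  invisible(x)
}

#' @export
as_tibble.displacement_field <- function(x, ...) {
  g <- field_node_coords(x)
  tibble(x_um = g$x, y_um = g$y, ux_um = as.vector(x$ux),
         uy_um = as.vector(x$uy))
}

#' @export
as_tibble.traction_field <- function(x, ...) {
  g <- field_node_coords(x)
  tibble(x_um = g$x, y_um = g$y, tx_pa = as.vector(x$tx),
         ty_pa = as.vector(x$ty))
}

field_node_coords <- function(f) {
  m <- if (!is.null(f$ux)) f$ux else f$tx
  h <- f$grid_spacing_px * f$pixel_size_um
  list(
    x = (rep(seq_len(ncol(m)), each = nrow(m)) - 0.5) * h +
      f$origin_px[2] * f$pixel_size_um,
    y = (rep(seq_len(nrow(m)), times = ncol(m)) - 0.5) * h +
      f$origin_px[1] * f$pixel_size_um
  )
}

field_spacing_um <- function(f) f$grid_spacing_px * f$pixel_size_um

# ---- Boussinesq Green tensor in Fourier space --------------------------------

# Components of G(k) for a semi-infinite elastic half-space:
#   G(k) = 2 (1 + nu) / (E k^3) *
#          [ (1-nu) k^2 + nu ky^2,  -nu kx ky ;
#            -nu kx ky,             (1-nu) k^2 + nu kx^2 ]
# with k in rad/um and E in Pa, so G is in um/Pa. The DC entry is left 0 and
# handled by forcing the zero-frequency traction/displacement mode to zero.
greens_tensor <- function(nr, nc, h_um, substrate) {
  kx_vec <- 2 * pi * fft_freq(nc, h_um)
  ky_vec <- 2 * pi * fft_freq(nr, h_um)
  KX <- matrix(kx_vec, nr, nc, byrow = TRUE)
  KY <- matrix(ky_vec, nr, nc)
  K2 <- KX^2 + KY^2
  K <- sqrt(K2)
  K[1, 1] <- Inf  # DC handled separately
  pref <- 2 * (1 + substrate$nu) / (substrate$E * K^3)
  list(
    g11 = pref * ((1 - substrate$nu) * K2 + substrate$nu * KY^2),
    g12 = pref * (-substrate$nu * KX * KY),
    g22 = pref * ((1 - substrate$nu) * K2 + substrate$nu * KX^2)
  )
}

fft_freq <- function(n, d = 1) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1) / (n * d)
}

#' Surface displacement generated by a traction field
#'
#' Forward Boussinesq solution on an elastic half-space, evaluated per
#' spatial frequency: `u(k) = G(k) T(k)`. Serves as the simulation oracle for
#' the FTTC inverse. The traction field must have zero mean (no net force).
#'
#' @param traction A [traction_field()] with zero DC component.
#' @param substrate A [substrate_model()].
#'
#' @return A [displacement_field()] on the same grid (um).
#' @export
forward_displacement <- function(traction, substrate) {
  stopifnot(inherits(traction, "traction_field"),
            inherits(substrate, "substrate_model"))
  tx <- traction$tx
  ty <- traction$ty
  scale <- max(abs(tx), abs(ty), 1e-300)
  if (abs(mean(tx)) > 1e-9 * scale || abs(mean(ty)) > 1e-9 * scale) {
    abort("Traction DC component must be zero (no net force).",
          class = "pabscope_validation_error")
  }
  h <- field_spacing_um(traction)
  G <- greens_tensor(nrow(tx), ncol(tx), h, substrate)
  ftx <- fft(tx)
  fty <- fft(ty)
  fux <- G$g11 * ftx + G$g12 * fty
  fuy <- G$g12 * ftx + G$g22 * fty
  fux[1, 1] <- 0 + 0i
  fuy[1, 1] <- 0 + 0i
  n <- length(tx)
  displacement_field(
    ux = Re(fft(fux, inverse = TRUE)) / n,
    uy = Re(fft(fuy, inverse = TRUE)) / n,
    grid_spacing_px = traction$grid_spacing_px,
    pixel_size_um = traction$pixel_size_um,
    origin_px = traction$origin_px
  )
}

#' Regularized Fourier-transform traction cytometry
#'
#' Inverts the Boussinesq relation per wavevector with zeroth-order Tikhonov
#' regularization: `T(k) = (G*G + lambda I)^-1 G* u(k)`. The mean (drift) of
#' the displacement field is removed and the DC traction mode is set to zero,
#' since the Green tensor diverges at `k = 0`. The default `lambda` is
#' 9.34e-9, applied under this package's units convention
#' (displacements in um, tractions in Pa, wavevectors in rad/um) — recorded
#' in the returned field, since such constants do not transfer across
#' conventions.
#'
#' @param u A [displacement_field()] on a regular grid of at least 16 x 16.
#' @param substrate A [substrate_model()].
#' @param lambda Tikhonov regularization parameter (>= 0).
#' @param pad Zero-pad to the next power of two with a cosine edge taper
#'   before inversion. Useful for cropped real images; leave off for periodic
#'   synthetic fields.
#'
#' @return A [traction_field()] (Pa) on the same grid.
#' @export
#' @examples
#' sc <- make_traction_scene(traction_scene_spec(seed = 1))
#' t_hat <- fttc(sc$displacement, sc$substrate, lambda = 0)
fttc <- function(u, substrate, lambda = 9.34e-9, pad = FALSE) {
  stopifnot(inherits(u, "displacement_field"),
            inherits(substrate, "substrate_model"))
  check_nonneg_scalar(lambda, "lambda")
  nr0 <- nrow(u$ux)
  nc0 <- ncol(u$ux)
  if (nr0 < 16 || nc0 < 16) {
    abort("Displacement grid must be at least 16 x 16.",
          class = "pabscope_validation_error")
  }
  ux <- u$ux - mean(u$ux)
  uy <- u$uy - mean(u$uy)
  if (pad) {
    tp <- cosine_taper(nr0, nc0)
    ux <- ux * tp
    uy <- uy * tp
    nr <- 2^ceiling(log2(nr0))
    nc <- 2^ceiling(log2(nc0))
    pad_mat <- function(m) {
      out <- matrix(0, nr, nc)
      out[seq_len(nr0), seq_len(nc0)] <- m
      out
    }
    ux <- pad_mat(ux)
    uy <- pad_mat(uy)
  } else {
    nr <- nr0
    nc <- nc0
  }
  h <- field_spacing_um(u)
  G <- greens_tensor(nr, nc, h, substrate)
  fux <- fft(ux)
  fuy <- fft(uy)
  # (G^2 + lambda I)^{-1} G u, with G real symmetric 2x2 per wavevector
  a11 <- G$g11^2 + G$g12^2 + lambda
  a12 <- G$g12 * (G$g11 + G$g22)
  a22 <- G$g22^2 + G$g12^2 + lambda
  b1 <- G$g11 * fux + G$g12 * fuy
  b2 <- G$g12 * fux + G$g22 * fuy
  det <- a11 * a22 - a12^2
  det[det == 0] <- Inf
  ftx <- (a22 * b1 - a12 * b2) / det
  fty <- (a11 * b2 - a12 * b1) / det
  ftx[1, 1] <- 0 + 0i
  fty[1, 1] <- 0 + 0i
  n <- nr * nc
  tx <- Re(fft(ftx, inverse = TRUE)) / n
  ty <- Re(fft(fty, inverse = TRUE)) / n
  tx <- tx[seq_len(nr0), seq_len(nc0)]
  ty <- ty[seq_len(nr0), seq_len(nc0)]
  tx <- tx - mean(tx)
  ty <- ty - mean(ty)
  traction_field(tx, ty, u$grid_spacing_px, u$pixel_size_um, u$origin_px,
                 lambda_used = lambda)
}

# Tukey-style cosine taper over the outer 10% of each edge.
cosine_taper <- function(nr, nc, frac = 0.1) {
  taper_1d <- function(n) {
    w <- rep(1, n)
    m <- max(1L, floor(frac * n))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[seq_len(m)] <- ramp
    w[n + 1 - seq_len(m)] <- ramp
    w
  }
  outer(taper_1d(nr), taper_1d(nc))
}
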