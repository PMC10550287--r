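#' Specification of a synthetic cell phantom
#'
#' Phantoms emulate the two morphologies scored by the PAB pipeline: round
#' cells whose F-actin is concentrated in a cosine-tapered peripheral ring
#' (`"pab"`), and elongated polarized cells with longitudinal stress-fiber
#' ridges and little border enrichment (`"polarized"`).
#'
#' @param phenotype `"pab"` or `"polarized"`.
#' @param image_size_px Length-2 integer (rows, cols).
#' @param pixel_size_um Pixel size (um).
#' @param equivalent_radius_um Radius of the equal-area circle (um).
#' @param axis_ratio Major/minor axis ratio (>= 1); a PAB phantom must stay
#'   near-round (<= 1.3).
#' @param ring_width_frac Width of the peripheral ring as a fraction of the
#'   (elliptical) radius, in (0, 1].
#' @param ring_intensity_share Target share of total actin intensity in the
#'   ring, in \[0, 1\].
#' @param background_level Constant background added outside and inside (AU).
#' @param noise_sd Gaussian noise sd (AU).
#' @param orientation_rad Major-axis orientation, counter-clockwise from +x.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A `phantom_cell_spec` list.
#' @export
phantom_cell_spec <- function(phenotype = c("pab", "polarized"),
                              image_size_px = c(192L, 192L),
                              pixel_size_um = 0.4,
                              equivalent_radius_um = 20,
                              axis_ratio = if (phenotype[1] == "pab") 1 else 2.5,
                              ring_width_frac = 0.2,
                              ring_intensity_share =
                                if (phenotype[1] == "pab") 0.75 else 0.25,
                              background_level = 20,
                              noise_sd = 0,
                              orientation_rad = 0,
                              seed = 1L) {
  phenotype <- match.arg(phenotype)
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 8))
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(equivalent_radius_um, "equivalent_radius_um")
  if (axis_ratio < 1) {
    abort("`axis_ratio` must be >= 1.", class = "pabscope_validation_error")
  }
  if (phenotype == "pab" && axis_ratio > 1.3) {
    abort("A pab phantom must have axis_ratio <= 1.3.",
          class = "pabscope_validation_error")
  }
  check_fraction(ring_width_frac, "ring_width_frac", open_lower = TRUE)
  check_fraction(ring_intensity_share, "ring_intensity_share")
  check_nonneg_scalar(background_level, "background_level")
  check_nonneg_scalar(noise_sd, "noise_sd")
  structure(
    list(phenotype = phenotype,
         image_size_px = as.integer(image_size_px),
         pixel_size_um = pixel_size_um,
         equivalent_radius_um = equivalent_radius_um,
         axis_ratio = axis_ratio,
         ring_width_frac = ring_width_frac,
         ring_intensity_share = ring_intensity_share,
         background_level = background_level,
         noise_sd = noise_sd,
         orientation_rad = orientation_rad,
         seed = as.integer(seed)),
    class = "phantom_cell_spec"
  )
}

#' Render a cell phantom with known ground truth
#'
#' Draws an elliptical cell (a disk when `axis_ratio = 1`) whose intensity is
#' split between a peripheral ring (cosine-tapered over the outer
#' `ring_width_frac` of the radius) and the interior (uniform plus phenotype
#' texture: sparse puncta for PAB cells, longitudinal ridges for polarized
#' cells), scaled so the ring holds exactly `ring_intensity_share` of the
#' total cell intensity before noise.
#'
#' @param spec A [phantom_cell_spec()].
#'
#' @return A list: `image` ([intensity_image()]), `mask` (ground-truth
#'   [cell_mask()]), `border_fraction` (ground-truth ring intensity share,
#'   measured with the generator's own band), `circularity` (analytic, via
#'   Ramanujan's ellipse perimeter), `spec`.
#' @export
#' @examples
#' ph <- make_cell_phantom(phantom_cell_spec("pab", seed = 7))
#' ph$border_fraction
make_cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_cell_spec"))
  nr <- spec$image_size_px[1]
  nc <- spec$image_size_px[2]
  r_px <- spec$equivalent_radius_um / spec$pixel_size_um
  a <- r_px * sqrt(spec$axis_ratio)   # semi-major (px)
  b <- r_px / sqrt(spec$axis_ratio)   # semi-minor (px)
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  ext <- sqrt((a * cos(spec$orientation_rad))^2 +
              (b * sin(spec$orientation_rad))^2)
  eyt <- sqrt((a * sin(spec$orientation_rad))^2 +
              (b * cos(spec$orientation_rad))^2)
  if (ext > 0.45 * nc || eyt > 0.45 * nr) {  # centered cell, >= 10% margin
    abort("Cell does not fit inside the image with a 10% margin.",
          class = "pabscope_geometry_error")
  }

  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dx <- col - cx
  dy <- row - cy
  co <- cos(spec$orientation_rad)
  si <- sin(spec$orientation_rad)
  xr <- dx * co + dy * si    # along major axis
  yr <- -dx * si + dy * co   # along minor axis
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  mask <- rho <= 1

  ring_lo <- 1 - spec$ring_width_frac
  ring <- mask & rho >= ring_lo
  interior <- mask & !ring

  # cosine taper peaked mid-ring, zero at both ring edges
  ring_prof <- matrix(0, nr, nc)
  if (any(ring)) {
    u <- (rho[ring] - ring_lo) / spec$ring_width_frac
    ring_prof[ring] <- sin(pi * u)^2
  }

  int_prof <- matrix(0, nr, nc)
  if (any(interior)) {
    base <- 1
    tex <- if (spec$phenotype == "polarized") {
      # longitudinal stress-fiber ridges: intensity modulated across the
      # minor axis with ~6 px period
      0.8 * cos(2 * pi * yr[interior] / 6)^2
    } else {
      0.3 * cos(2 * pi * xr[interior] / 11)^2 *
        cos(2 * pi * yr[interior] / 13)^2
    }
    int_prof[interior] <- base + tex
  }

  s <- spec$ring_intensity_share
  sum_ring <- sum(ring_prof)
  sum_int <- sum(int_prof)
  if (s >= 1 || sum_int == 0) {
    int_prof[] <- 0
    ring_amp <- 1
  } else if (s <= 0 || sum_ring == 0) {
    ring_amp <- 0
  } else {
    ring_amp <- s * sum_int / ((1 - s) * sum_ring)
  }
  cell <- ring_amp * ring_prof + int_prof
  if (max(cell) > 0) cell <- cell * (800 / max(cell))

  # ground truth measured with the generator's own band definition
  total <- sum(cell[mask])
  gt_border <- if (total > 0) sum(cell[ring]) / total else NA_real_

  img <- cell + spec$background_level
  if (spec$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(spec$seed)
    img <- img + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  }
  img <- pmax(img, 0)

  list(
    image = intensity_image(img, spec$pixel_size_um, channel = "phalloidin"),
    mask = cell_mask(mask, spec$pixel_size_um),
    border_fraction = gt_border,
    circularity = ellipse_circularity(a, b),
    spec = spec
  )
}

#' Analytic circularity of an ellipse
#'
#' Uses Ramanujan's perimeter approximation
#' `P ~ pi * (3 (a + b) - sqrt((3a + b)(a + 3b)))`.
#'
#' @param a,b Semi-axes (any common unit).
#' @return Circularity `4 pi A / P^2`, clamped to 1.
#' @export
ellipse_circularity <- function(a, b) {
  p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  min(1, 4 * pi * (pi * a * b) / p^2)
}

#' Logical disk mask (test/fixture helper)
#'
#' @param nr,nc Image size in pixels.
#' @param r Disk radius (px).
#' @param cy,cx Center (row, col); defaults to the image center.
#' @return Logical matrix.
#' @export
disk_mask <- function(nr, nc, r, cy = (nr + 1) / 2, cx = (nc + 1) / 2) {
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (row - cy)^2 + (col - cx)^2 <= r^2
}

# ---- seed hygiene ------------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Stable sub-seed derivation so each sub-draw of a generator has its own
# stream (partial regeneration stays reproducible). Kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 9973) %% 2147483629
}
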