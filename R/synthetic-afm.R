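#' Simulate an AFM approach force curve
#'
#' Generates piezo-displacement / cantilever-deflection samples for a sphere
#' indenting an elastic half-space. Before contact (`z < z0_um`) the
#' deflection is zero; after contact the deflection `d` solves the
#' self-consistent Hertz balance `k d = 4 E sqrt(R) delta^{3/2} / (3 (1 -
#' mu^2))` with indentation `delta = (z - z0) - d`, so a round trip through
#' [fit_hertz()] recovers `E` exactly in the noiseless case.
#'
#' @param E_pa Cell modulus (Pa).
#' @param k_n_per_m Cantilever stiffness (N/m), default 0.00664 (a soft
#'   colloidal-probe cantilever).
#' @param R_um Probe tip radius (um), default 1.75 (3.5 um colloidal probe).
#' @param z0_um Contact point on the piezo axis (um).
#' @param z_range_um Length-2 numeric, piezo range; must span `z0_um`.
#' @param n_samples Number of samples across the range.
#' @param noise_sd_n Gaussian force noise sd (N), applied to the deflection
#'   as `noise / k`.
#' @param mu Poisson's ratio of the cell, default 0.5 (incompressible).
#' @param seed Integer seed.
#'
#' @return A `force_curve`: tibble with `z_um`, `d_um` plus attributes
#'   `k_n_per_m`, `R_um`, `z0_true_um`, `E_true_pa`.
#' @export
#' @examples
#' fc <- make_force_curve(E_pa = 10000, z0_um = 1, z_range_um = c(0, 3))
#' head(fc)
make_force_curve <- function(E_pa, k_n_per_m = 0.00664, R_um = 1.75,
                             z0_um = 1, z_range_um = c(0, 3),
                             n_samples = 200L, noise_sd_n = 0, mu = 0.5,
                             seed = 1L) {
  check_positive_scalar(E_pa, "E_pa")
  check_positive_scalar(k_n_per_m, "k_n_per_m")
  check_positive_scalar(R_um, "R_um")
  stopifnot(length(z_range_um) == 2L, diff(z_range_um) > 0)
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  check_nonneg_scalar(noise_sd_n, "noise_sd_n")

  z <- seq(z_range_um[1], z_range_um[2], length.out = n_samples)
  d <- hertz_deflection(z - z0_um, E_pa, k_n_per_m, R_um, mu)

  if (noise_sd_n > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    d <- d + rnorm(length(d), sd = noise_sd_n / k_n_per_m * 1e6)
  }

  force_curve(tibble(z_um = z, d_um = d), k_n_per_m = k_n_per_m, R_um = R_um,
              z0_true_um = z0_um, E_true_pa = E_pa)
}

#' Self-consistent Hertz deflection of a compliant cantilever
#'
#' Solves `k d = C ((zeta) - d)^{3/2}` for the deflection `d` at piezo travel
#' `zeta = z - z0` past contact (vectorized Newton iteration; `d = 0` before
#' contact). This is the exact forward model of an approach curve when the
#' indentation is the piezo travel minus the deflection.
#'
#' @param zeta_um Piezo travel past contact (um); may be negative.
#' @param E_pa Modulus (Pa).
#' @param k_n_per_m Cantilever stiffness (N/m).
#' @param R_um Tip radius (um).
#' @param mu Poisson's ratio.
#' @return Deflections (um), same length as `zeta_um`.
#' @export
hertz_deflection <- function(zeta_um, E_pa, k_n_per_m, R_um, mu = 0.5) {
  cc <- hertz_prefactor(E_pa, R_um, mu)
  zeta <- pmax(zeta_um, 0) * 1e-6
  d <- 0.5 * zeta
  for (it in 1:60) {
    delta <- pmax(zeta - d, 0)
    f <- k_n_per_m * d - cc * delta^1.5
    fp <- k_n_per_m + 1.5 * cc * sqrt(delta)
    step <- f / fp
    d <- pmin(pmax(d - step, 0), zeta)
    if (max(abs(step)) < 1e-18) break
  }
  d * 1e6
}

# F = 4 E sqrt(R) / (3 (1 - mu^2)) * delta^{3/2}, all SI
hertz_prefactor <- function(E_pa, R_um, mu) {
  if (mu >= 1 || mu < 0) {
    abort("Poisson ratio must be in [0, 1).", class = "pabscope_validation_error")
  }
  4 * E_pa * sqrt(R_um * 1e-6) / (3 * (1 - mu^2))
}

#' Construct a force-curve object
#'
#' @param samples Tibble with `z_um` (piezo) and `d_um` (deflection).
#' @param k_n_per_m Cantilever stiffness (N/m).
#' @param R_um Tip radius (um).
#' @param ... Extra attributes (e.g. ground truth) attached to the object.
#' @return A `force_curve` tibble.
#' @export
force_curve <- function(samples, k_n_per_m, R_um, ...) {
  stopifnot(is.data.frame(samples),
            all(c("z_um", "d_um") %in% names(samples)))
  check_positive_scalar(k_n_per_m, "k_n_per_m")
  check_positive_scalar(R_um, "R_um")
  out <- as_tibble(samples)
  attr(out, "k_n_per_m") <- k_n_per_m
  attr(out, "R_um") <- R_um
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("force_curve", class(out))
  out
}
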