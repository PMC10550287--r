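#' Closed-form Hertz force for a spherical indenter
#'
#' `F = 4 E sqrt(R) delta^{3/2} / (3 (1 - mu^2))`, all SI internally:
#' `E` in Pa, tip radius and indentation in micrometres, force in newtons.
#'
#' @param E_pa Elastic modulus (Pa).
#' @param R_um Tip radius (um).
#' @param delta_um Indentation depth(s) (um, >= 0).
#' @param mu Poisson's ratio in \[0, 1).
#'
#' @return Force(s) in newtons.
#' @export
#' @examples
#' hertz_force(10000, 1.75, 0.5)  # ~8.32e-9 N
hertz_force <- function(E_pa, R_um, delta_um, mu = 0.5) {
  check_positive_scalar(E_pa, "E_pa")
  check_positive_scalar(R_um, "R_um")
  if (any(delta_um < 0)) {
    abort("Indentation must be >= 0.", class = "pabscope_validation_error")
  }
  hertz_prefactor(E_pa, R_um, mu) * (delta_um * 1e-6)^1.5
}

#' Locate the contact point of an approach force curve
#'
#' Grid search over candidate contact points: for each candidate `z0` the
#' pre-contact samples get a linear baseline fit and the post-contact samples
#' a Hertz fit (linear in `E` given `delta^{3/2}`); the `z0` minimizing the
#' total squared error of this piecewise model wins. Fails when no Hertzian
#' rise is present (flat curve).
#'
#' @param curve A [force_curve()].
#' @param mu Poisson's ratio used in the Hertz branch.
#' @param min_rise_factor Post-contact deflection rise, in units of the
#'   baseline residual spread, below which no contact is declared.
#' @param max_baseline_slope Largest admissible pre-contact baseline tilt
#'   (deflection per piezo travel). Optical-interference tilts are gentle;
#'   the cap keeps the baseline from swallowing a near-linear contact rise
#'   when the cell is much stiffer than the cantilever.
#'
#' @return Contact point `z0` (um) with attributes `baseline` (intercept,
#'   slope of the pre-contact deflection trend).
#' @export
find_contact_point <- function(curve, mu = 0.5, min_rise_factor = 5,
                               max_baseline_slope = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z_um
  d <- curve$d_um
  n <- length(z)
  if (n < 20L) {
    abort("Need at least 20 samples.", class = "pabscope_validation_error")
  }
  k <- attr(curve, "k_n_per_m")
  R <- attr(curve, "R_um")
  ord <- order(z)
  z <- z[ord]
  d <- d[ord]

  # piecewise model residual for a continuous candidate z0: linear baseline
  # over pre-contact samples, Hertz (linear in E) over post-contact samples
  piecewise_fit <- function(z0) {
    pre <- which(z <= z0)
    post <- which(z > z0)
    if (length(pre) < 5L) return(NULL)
    bfit <- stats::lm.fit(cbind(1, z[pre]), d[pre])
    base <- bfit$coefficients
    if (abs(base[2]) > max_baseline_slope) return(NULL)
    sse_pre <- sum(bfit$residuals^2)
    d_corr <- d[post] - (base[1] + base[2] * z[post])
    delta <- (z[post] - z0) - d_corr
    keep <- delta > 0
    if (sum(keep) < 5L) return(NULL)
    Fpost <- k * d_corr[keep] * 1e-6
    x <- 4 * sqrt(R * 1e-6) * (delta[keep] * 1e-6)^1.5 / (3 * (1 - mu^2))
    E_hat <- sum(Fpost * x) / sum(x^2)
    if (!is.finite(E_hat)) return(NULL)
    # samples with delta <= 0 predict zero force: their measured force is
    # pure residual, otherwise late contact candidates win by dropping data
    sse_post <- (sum((Fpost - E_hat * x)^2) +
                   sum((k * d_corr[!keep] * 1e-6)^2)) / (k * 1e-6)^2
    list(sse = sse_pre + sse_post, z0 = z0, E = E_hat, base = base)
  }

  lo <- 5L
  hi <- n - 10L
  best <- list(sse = Inf, z0 = NA_real_, E = NA_real_, base = c(0, 0))
  best_ci <- NA_integer_
  for (ci in lo:hi) {
    fit <- piecewise_fit(z[ci])
    if (!is.null(fit) && fit$sse < best$sse) {
      best <- fit
      best_ci <- ci
    }
  }
  if (!is.finite(best$z0) || is.na(best$E) || best$E <= 0) {
    abort("No post-contact rise detected.", class = "pabscope_no_contact")
  }
  # joint polish in the deflection domain: noise lives on d, so the proper
  # objective compares measured deflections with the exact self-consistent
  # forward model rather than regressing F on a noisy delta^{3/2}
  deflection_sse <- function(par) {
    z0 <- par[1]
    E <- exp(par[2])
    pre <- which(z <= z0)
    if (length(pre) < 5L || length(pre) > n - 10L) return(Inf)
    bfit <- stats::lm.fit(cbind(1, z[pre]), d[pre])
    if (abs(bfit$coefficients[2]) > max_baseline_slope) return(Inf)
    pred <- bfit$coefficients[1] + bfit$coefficients[2] * z +
      hertz_deflection(z - z0, E, k, R, mu)
    sum((d - pred)^2)
  }
  opt <- stats::optim(c(best$z0, log(best$E)), deflection_sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  if (is.finite(opt$value) && opt$value <= deflection_sse(c(best$z0, log(best$E)))) {
    z0_new <- opt$par[1]
    pre <- which(z <= z0_new)
    bfit <- stats::lm.fit(cbind(1, z[pre]), d[pre])
    best <- list(sse = opt$value, z0 = z0_new, E = exp(opt$par[2]),
                 base = bfit$coefficients)
  }
  # flat-curve guard: the rise beyond the baseline must dominate its spread
  base_resid <- d - (best$base[1] + best$base[2] * z)
  pre_sd <- max(sd(base_resid[z <= best$z0]), 1e-9)
  if (max(base_resid[z > best$z0]) < min_rise_factor * pre_sd) {
    abort("No post-contact rise detected.", class = "pabscope_no_contact")
  }
  structure(best$z0, baseline = unname(best$base))
}

#' Convert a force curve to force-indentation data
#'
#' `F = k d` (SI) and `delta = (z - z0) - d`: the piezo travel past contact
#' minus the cantilever deflection. Only samples with positive indentation
#' are returned. A linear pre-contact baseline (from [find_contact_point()])
#' may be removed first via `baseline`.
#'
#' @param curve A [force_curve()].
#' @param z0_um Contact point (um).
#' @param baseline Optional length-2 `(intercept, slope)` deflection baseline
#'   to subtract.
#'
#' @return Tibble with `delta_um` and `force_n`.
#' @export
force_indentation <- function(curve, z0_um, baseline = c(0, 0)) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z_um
  if (z0_um < min(z) || z0_um > max(z)) {
    abort("Contact point outside curve range.",
          class = "pabscope_validation_error")
  }
  k <- attr(curve, "k_n_per_m")
  d <- curve$d_um - (baseline[1] + baseline[2] * z)
  delta <- (z - z0_um) - d
  keep <- z > z0_um & delta > 0
  if (!any(keep)) {
    abort("All indentations non-positive (rigid contact?).",
          class = "pabscope_empty_indentation")
  }
  tibble(delta_um = delta[keep], force_n = k * d[keep] * 1e-6)
}

#' Fit the Hertz modulus to force-indentation data
#'
#' The model is linear in `E` given `delta^{3/2}`, so the least-squares
#' modulus has the closed form `E = sum(F x) / sum(x^2)` with
#' `x = 4 sqrt(R) delta^{3/2} / (3 (1 - mu^2))`.
#'
#' @param data Tibble with `delta_um`, `force_n` (>= 10 points).
#' @param R_um Tip radius (um).
#' @param mu Poisson's ratio, default 0.5 (incompressible cell).
#' @param contact_point_um Optional `z0` carried into the result.
#'
#' @return A `hertz_fit` object (see [tidy.hertz_fit()]).
#' @export
fit_hertz <- function(data, R_um = 1.75, mu = 0.5, contact_point_um = NA_real_) {
  stopifnot(is.data.frame(data),
            all(c("delta_um", "force_n") %in% names(data)))
  if (nrow(data) < 10L) {
    abort("Need >= 10 post-contact points.",
          class = "pabscope_validation_error")
  }
  check_positive_scalar(R_um, "R_um")
  x <- 4 * sqrt(R_um * 1e-6) * (data$delta_um * 1e-6)^1.5 / (3 * (1 - mu^2))
  E_hat <- sum(data$force_n * x) / sum(x^2)
  if (!is.finite(E_hat) || E_hat <= 0) {
    abort("Fit produced a non-positive modulus.", class = "pabscope_fit_failed")
  }
  resid <- data$force_n - E_hat * x
  structure(
    list(modulus_pa = E_hat,
         contact_point_um = contact_point_um,
         poisson_ratio = mu,
         tip_radius_um = R_um,
         rms_residual_n = sqrt(mean(resid^2)),
         n_points_used = nrow(data),
         data = data),
    class = "hertz_fit"
  )
}

#' Fit a full force curve end to end
#'
#' Contact-point search, baseline removal, force-indentation conversion, and
#' Hertz fit in one call.
#'
#' @param curve A [force_curve()].
#' @param mu Poisson's ratio.
#' @return A `hertz_fit`.
#' @export
fit_force_curve <- function(curve, mu = 0.5) {
  z0 <- find_contact_point(curve, mu = mu)
  fi <- force_indentation(curve, as.numeric(z0), baseline = attr(z0, "baseline"))
  fit_hertz(fi, R_um = attr(curve, "R_um"), mu = mu,
            contact_point_um = as.numeric(z0))
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.1f Pa (z0 = %.3g um, mu = %.2f, R = %.3g um, %d points, rms %.3g N)\n",
    x$modulus_pa, x$contact_point_um, x$poisson_ratio, x$tip_radius_um,
    x$n_points_used, x$rms_residual_n
  ))
  invisible(x)
}

#' Tidy a Hertz fit
#'
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit parameters.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(
    term = "modulus_pa",
    estimate = x$modulus_pa,
    contact_point_um = x$contact_point_um,
    poisson_ratio = x$poisson_ratio,
    tip_radius_um = x$tip_radius_um
  )
}

#' @rdname tidy.hertz_fit
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(
    modulus_pa = x$modulus_pa,
    contact_point_um = x$contact_point_um,
    rms_residual_n = x$rms_residual_n,
    n_points_used = x$n_points_used
  )
}

#' Read an AFM force curve from CSV
#'
#' Expected columns: `z_um`, `d_um` (or `deflection_um`).
#'
#' @param path CSV path.
#' @param k_n_per_m Cantilever stiffness (N/m).
#' @param R_um Tip radius (um).
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, k_n_per_m = 0.00664, R_um = 1.75) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("deflection_um" %in% names(df) && !"d_um" %in% names(df)) {
    df <- dplyr::rename(df, d_um = "deflection_um")
  }
  force_curve(df, k_n_per_m = k_n_per_m, R_um = R_um)
}
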