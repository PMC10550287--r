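#' Align the reference bead image to the stressed image
#'
#' Estimates the rigid translation between the two images by the peak of
#' their FFT cross-correlation (sub-pixel via a Gaussian 3-point estimator)
#' and returns the reference resampled onto the stressed frame (Fourier
#' shift). Registration fails when the correlation peak does not stand out
#' from the sidelobes (no coherent bead pattern).
#'
#' @param reference,stressed [intensity_image()]s of identical geometry.
#' @param min_peak_ratio Minimum peak / strongest-sidelobe ratio, default 1.3.
#'
#' @return List: `aligned` ([intensity_image()]) and `shift_px`
#'   (length-2 `(row, col)` shift applied to the reference).
#' @export
register_reference <- function(reference, stressed, min_peak_ratio = 1.3) {
  stopifnot(inherits(reference, "intensity_image"),
            inherits(stressed, "intensity_image"),
            all(dim(reference$pixels) == dim(stressed$pixels)))
  a <- reference$pixels - mean(reference$pixels)
  b <- stressed$pixels - mean(stressed$pixels)
  xc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / length(a)
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  nr <- nrow(xc)
  nc <- ncol(xc)

  # peak vs sidelobe outside a 5-px exclusion zone (periodic distance)
  di <- pmin(abs(row(xc) - pk[1]), nr - abs(row(xc) - pk[1]))
  dj <- pmin(abs(col(xc) - pk[2]), nc - abs(col(xc) - pk[2]))
  sidelobe <- max(xc[di > 5 | dj > 5])
  if (!is.finite(sidelobe) || sidelobe <= 0 ||
      max(xc) / sidelobe < min_peak_ratio) {
    abort("No distinct correlation peak; registration failed.",
          class = "pabscope_registration_failed")
  }

  sub <- subpixel_peak(xc, pk[1], pk[2])
  shift_row <- wrap_shift(pk[1] - 1 + sub[1], nr)
  shift_col <- wrap_shift(pk[2] - 1 + sub[2], nc)
  aligned <- fourier_shift(reference$pixels, shift_row, shift_col)
  list(
    aligned = intensity_image(pmax(aligned, 0), reference$pixel_size_um,
                              reference$channel),
    shift_px = c(row = shift_row, col = shift_col)
  )
}

wrap_shift <- function(s, n) ifelse(s > n / 2, s - n, s)

# 3-point Gaussian sub-pixel interpolation along each axis (PIV standard),
# falling back to a parabola when log-values are unusable.
subpixel_peak <- function(xc, i, j) {
  nr <- nrow(xc)
  nc <- ncol(xc)
  at <- function(ii, jj) xc[(ii - 1) %% nr + 1, (jj - 1) %% nc + 1]
  axis_offset <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
      den <- log(cm) - 2 * log(c0) + log(cp)
      if (den < 0) return(0.5 * (log(cm) - log(cp)) / den)
    }
    den <- cm - 2 * c0 + cp
    if (den < 0) 0.5 * (cm - cp) / den else 0
  }
  c(
    axis_offset(at(i - 1, j), at(i, j), at(i + 1, j)),
    axis_offset(at(i, j - 1), at(i, j), at(i, j + 1))
  )
}

# Exact sub-pixel translation via the Fourier shift theorem.
fourier_shift <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  kr <- 2 * pi * fft_freq(nr)
  kc <- 2 * pi * fft_freq(nc)
  ph <- exp(-1i * (outer(kr * dr, rep(1, nc)) + outer(rep(1, nr), kc * dc)))
  Re(fft(fft(m) * ph, inverse = TRUE)) / length(m)
}

#' Estimate bead displacements on a regular grid
#'
#' Windowed matching between the (aligned) reference and stressed bead
#' images: for each grid node, the integer displacement is found by
#' normalized cross-correlation of a `window_px` window over a local search
#' radius, then refined to sub-pixel precision by iterative gradient-based
#' (Lucas–Kanade) flow on the bilinearly warped window. Windows with too
#' little texture are flagged invalid and filled by interpolation from their
#' valid neighbours.
#'
#' @param reference,stressed [intensity_image()]s of identical geometry
#'   (register first with [register_reference()]).
#' @param window_px Matching window size (>= 8), default 16.
#' @param grid_spacing_px Node spacing (px); defaults to `window_px / 2`.
#' @param search_px Integer search radius (px).
#' @param min_texture_sd Minimum within-window intensity sd for a window to
#'   count as textured.
#' @param min_ncc Minimum normalized cross-correlation at the matched shift;
#'   windows below it (e.g. containing no bead) are invalid and interpolated.
#'
#' @return A [displacement_field()] (um).
#' @export
estimate_displacements <- function(reference, stressed, window_px = 16L,
                                   grid_spacing_px = NULL, search_px = 8L,
                                   min_texture_sd = 1e-3, min_ncc = 0.5) {
  stopifnot(inherits(reference, "intensity_image"),
            inherits(stressed, "intensity_image"),
            all(dim(reference$pixels) == dim(stressed$pixels)))
  window_px <- check_count(window_px, "window_px", min = 8L)
  grid_spacing_px <- grid_spacing_px %||% max(1L, window_px %/% 2L)
  grid_spacing_px <- check_count(grid_spacing_px, "grid_spacing_px")
  search_px <- check_count(search_px, "search_px")
  ref <- reference$pixels
  def <- stressed$pixels
  nr <- nrow(ref)
  nc <- ncol(ref)
  hw <- window_px %/% 2L

  rows <- seq(hw + search_px + 1, nr - hw - search_px, by = grid_spacing_px)
  cols <- seq(hw + search_px + 1, nc - hw - search_px, by = grid_spacing_px)
  if (length(rows) < 2L || length(cols) < 2L) {
    abort("Image too small for the requested window/search sizes.",
          class = "pabscope_validation_error")
  }
  ux <- matrix(NA_real_, length(rows), length(cols))
  uy <- matrix(NA_real_, length(rows), length(cols))

  win_idx <- seq_len(window_px) - hw - 1L  # offsets relative to node
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      r0 <- rows[ri]
      c0 <- cols[ci]
      a <- ref[r0 + win_idx, c0 + win_idx]
      if (sd(a) < min_texture_sd) next
      ishift <- ncc_integer_shift(a, def, r0, c0, win_idx, search_px)
      if (ishift[3] < min_ncc) next
      d <- lk_refine(a, def, r0, c0, win_idx, ishift[1], ishift[2])
      uy[ri, ci] <- d[1]
      ux[ri, ci] <- d[2]
    }
  }
  filled <- fill_invalid(ux, uy)
  px <- reference$pixel_size_um
  displacement_field(filled$ux * px, filled$uy * px,
                     grid_spacing_px = grid_spacing_px, pixel_size_um = px,
                     origin_px = c(rows[1] - grid_spacing_px / 2,
                                   cols[1] - grid_spacing_px / 2))
}

# Integer-shift NCC over a square search neighbourhood; returns
# (row shift, col shift, best score).
ncc_integer_shift <- function(a, def, r0, c0, win_idx, search) {
  a0 <- a - mean(a)
  na <- sqrt(sum(a0^2))
  if (na == 0) return(c(0L, 0L, 0))
  best <- -Inf
  best_sh <- c(0L, 0L)
  for (dr in -search:search) {
    for (dc in -search:search) {
      b <- def[r0 + dr + win_idx, c0 + dc + win_idx]
      b0 <- b - mean(b)
      nb <- sqrt(sum(b0^2))
      if (nb == 0) next
      score <- sum(a0 * b0) / (na * nb)
      if (score > best) {
        best <- score
        best_sh <- c(dr, dc)
      }
    }
  }
  c(best_sh, best)
}

# Iterative Lucas-Kanade refinement around an integer displacement; the
# stressed window is resampled bilinearly at the current estimate. The
# refinement is a sub-pixel correction: if it wanders more than `max_step`
# from the correlation match it is deemed divergent and discarded.
lk_refine <- function(a, def, r0, c0, win_idx, dr, dc, iters = 5L,
                      max_step = 1.5) {
  dr0 <- dr
  dc0 <- dc
  n <- length(win_idx)
  gy <- (rbind(a[-1, ], a[n, ]) - rbind(a[1, ], a[-n, ])) / 2
  gx <- (cbind(a[, -1], a[, n]) - cbind(a[, 1], a[, -n])) / 2
  g11 <- sum(gy * gy)
  g12 <- sum(gy * gx)
  g22 <- sum(gx * gx)
  det <- g11 * g22 - g12^2
  if (det <= 1e-12) return(c(dr, dc))
  rows_w <- r0 + win_idx
  cols_w <- c0 + win_idx
  R <- matrix(rep(rows_w, times = n), n, n)
  C <- matrix(rep(cols_w, each = n), n, n)
  for (it in seq_len(iters)) {
    b <- bilinear(def, as.vector(R) + dr, as.vector(C) + dc)
    it_err <- matrix(b, n, n) - a
    e1 <- -sum(gy * it_err)
    e2 <- -sum(gx * it_err)
    ddr <- (g22 * e1 - g12 * e2) / det
    ddc <- (g11 * e2 - g12 * e1) / det
    dr <- dr + ddr
    dc <- dc + ddc
    if (abs(dr - dr0) > max_step || abs(dc - dc0) > max_step) {
      return(c(dr0, dc0))
    }
    if (abs(ddr) < 1e-4 && abs(ddc) < 1e-4) break
  }
  c(dr, dc)
}

# Fill invalid (NA) nodes from valid neighbours by iterative local means.
fill_invalid <- function(ux, uy) {
  bad <- is.na(ux)
  if (!any(bad)) return(list(ux = ux, uy = uy))
  if (all(bad)) {
    abort("No textured windows; displacement field undefined.",
          class = "pabscope_validation_error")
  }
  for (pass in seq_len(64L)) {
    bad_idx <- which(is.na(ux), arr.ind = TRUE)
    if (nrow(bad_idx) == 0L) break
    for (k in seq_len(nrow(bad_idx))) {
      i <- bad_idx[k, 1]
      j <- bad_idx[k, 2]
      ii <- max(1, i - 1):min(nrow(ux), i + 1)
      jj <- max(1, j - 1):min(ncol(ux), j + 1)
      nb <- ux[ii, jj]
      if (any(!is.na(nb))) {
        ux[i, j] <- mean(nb, na.rm = TRUE)
        uy[i, j] <- mean(uy[ii, jj], na.rm = TRUE)
      }
    }
  }
  ux[is.na(ux)] <- 0
  uy[is.na(uy)] <- 0
  list(ux = ux, uy = uy)
}
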