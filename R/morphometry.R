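#' PAB classification thresholds
#'
#' The peripheral actin band (PAB) phenotype is called when a cell keeps more
#' than half of its (background-subtracted) actin intensity in a peripheral
#' border band *and* its circularity exceeds 0.6. Both inequalities are
#' strict. `band_fraction` sets the border-band depth as a fraction of the
#' cell's equivalent radius.
#'
#' @param f_thresh Border actin fraction threshold, default 0.50.
#' @param c_thresh Circularity threshold, default 0.60.
#' @param band_fraction Border-band depth as a fraction of equivalent radius,
#'   default 0.20.
#'
#' @return A `pab_thresholds` list.
#' @export
#' @examples
#' pab_thresholds()
pab_thresholds <- function(f_thresh = 0.50, c_thresh = 0.60,
                           band_fraction = 0.20) {
  check_fraction(f_thresh, "f_thresh", open_lower = TRUE, open_upper = TRUE)
  check_fraction(c_thresh, "c_thresh", open_lower = TRUE, open_upper = TRUE)
  check_fraction(band_fraction, "band_fraction", open_lower = TRUE)
  structure(
    list(f_thresh = f_thresh, c_thresh = c_thresh,
         band_fraction = band_fraction),
    class = "pab_thresholds"
  )
}

#' Segment the dominant cell from a fluorescence image
#'
#' Smooths with a Gaussian (sigma = 1 px), thresholds (Otsu by default),
#' labels 8-connected components, keeps the largest one at least
#' `min_area_um2` large (ties broken by total intensity), and fills holes.
#'
#' @param image An [intensity_image()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param min_area_um2 Minimum acceptable cell area (um^2).
#' @param fixed_threshold Threshold intensity when `threshold_method = "fixed"`.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels.
#'
#' @return A [cell_mask()].
#' @export
segment_cell <- function(image, threshold_method = c("otsu", "fixed"),
                         min_area_um2 = 50, fixed_threshold = NULL,
                         smooth_sigma_px = 1) {
  stopifnot(inherits(image, "intensity_image"))
  threshold_method <- match.arg(threshold_method)
  px <- image$pixels
  if (length(px) == 0L) {
    abort("Empty image.", class = "pabscope_validation_error")
  }
  sm <- gaussian_blur(px, smooth_sigma_px)
  thr <- switch(threshold_method,
    otsu = otsu_threshold(sm),
    fixed = {
      check_nonneg_scalar(fixed_threshold, "fixed_threshold")
      fixed_threshold
    }
  )
  fg <- sm > thr
  min_area_px <- min_area_um2 / image$pixel_size_um^2
  if (!any(fg)) {
    abort("No cell found above threshold.", class = "pabscope_no_cell_found")
  }
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) {
    abort(sprintf("No component reaches min area of %.1f px.", min_area_px),
          class = "pabscope_no_cell_found")
  }
  best <- keep[order(
    areas[keep],
    vapply(keep, function(i) sum(px[lab == i]), numeric(1))
  )]
  best <- best[length(best)]
  mask <- lab == best
  mask <- EBImage::fillHull(mask) > 0
  cell_mask(matrix(as.logical(mask), nrow(px), ncol(px)),
            image$pixel_size_um, component_id = best)
}

#' Area, perimeter, and circularity of a cell mask
#'
#' Area is the foreground pixel count times the pixel area. The perimeter is
#' measured sub-pixel: the mask is lightly smoothed (Gaussian, sigma = 1 px)
#' and the 0.5-level contour polygon length is summed (marching squares), which
#' removes the staircase bias that makes a pixel-edge perimeter report a
#' circle's circularity as about 0.79. Circularity `4*pi*A/P^2` is clamped to
#' 1, the particle-analysis convention.
#'
#' @param mask A [cell_mask()] (or logical matrix).
#' @param pixel_size_um Pixel size in micrometres; defaults to the mask's own.
#'
#' @return A one-row tibble with `area_um2`, `perimeter_um`, `circularity`.
#' @export
#' @examples
#' m <- disk_mask(64, 64, r = 20)
#' measure_shape(cell_mask(m, 1))
measure_shape <- function(mask, pixel_size_um = NULL) {
  m <- mask_matrix(mask)
  pixel_size_um <- pixel_size_um %||% mask$pixel_size_um
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  n_fg <- sum(m)
  if (n_fg == 0L) {
    abort("Empty mask.", class = "pabscope_validation_error")
  }
  area_um2 <- n_fg * pixel_size_um^2
  perimeter_um <- mask_perimeter_px(m) * pixel_size_um
  circ <- min(1, 4 * pi * area_um2 / perimeter_um^2)
  tibble(area_um2 = area_um2, perimeter_um = perimeter_um, circularity = circ)
}

# Sub-pixel perimeter: 0.5-level contour of the sigma=1 smoothed indicator.
# Padding guarantees closed contours for masks touching the frame.
mask_perimeter_px <- function(m) {
  pad <- 4L
  big <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m * 1.0
  sm <- gaussian_blur(big, 1)
  cl <- grDevices::contourLines(seq_len(nrow(big)), seq_len(ncol(big)), sm,
                                levels = 0.5)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(p) {
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  }, numeric(1)))
}

#' Extract the peripheral border band of a mask
#'
#' The band is the set of foreground pixels within depth `d` of the
#' background, where `d = band_fraction * equivalent_radius` (px, rounded,
#' at least 1). Depth is Euclidean via a distance transform, so the band is
#' the mask minus its erosion by a disk of radius `d`. `band_fraction = 1`
#' returns the whole mask.
#'
#' @param mask A [cell_mask()].
#' @param band_fraction Band depth as a fraction of the equivalent radius,
#'   in (0, 1].
#'
#' @return A [cell_mask()] of the band (subset of `mask`).
#' @export
border_band <- function(mask, band_fraction = 0.20) {
  m <- mask_matrix(mask)
  check_fraction(band_fraction, "band_fraction", open_lower = TRUE)
  n_fg <- sum(m)
  if (n_fg == 0L) abort("Empty mask.", class = "pabscope_validation_error")
  if (band_fraction == 1) {
    return(cell_mask(m, mask$pixel_size_um, mask$component_id))
  }
  r_eq <- sqrt(n_fg / pi)
  d <- max(1, round(band_fraction * r_eq))
  dist <- EBImage::distmap(m * 1.0)
  band <- m & (dist <= d)
  if (!any(band)) band <- m  # erosion would empty the mask
  cell_mask(band, mask$pixel_size_um, mask$component_id)
}

#' Fraction of actin intensity in the border band
#'
#' `f = sum_band max(I - background, 0) / sum_mask max(I - background, 0)`.
#'
#' @param image An [intensity_image()].
#' @param mask Whole-cell [cell_mask()].
#' @param band Border-band [cell_mask()]; must be a subset of `mask`.
#' @param background Scalar background level subtracted before summing. The
#'   default is the median intensity outside the mask.
#'
#' @return Scalar in \[0, 1\].
#' @export
border_actin_fraction <- function(image, mask, band, background = NULL) {
  stopifnot(inherits(image, "intensity_image"))
  m <- mask_matrix(mask)
  b <- mask_matrix(band)
  if (any(b & !m)) {
    abort("`band` must be a subset of `mask`.",
          class = "pabscope_validation_error")
  }
  px <- image$pixels
  background <- background %||%
    (if (any(!m)) stats::median(px[!m]) else 0)
  check_nonneg_scalar(background, "background")
  net <- pmax(px - background, 0)
  total <- sum(net[m])
  if (total <= 0) {
    abort("Background-subtracted cell intensity is zero; fraction undefined.",
          class = "pabscope_undefined_fraction")
  }
  sum(net[b]) / total
}

#' Classify a cell as PAB
#'
#' A cell is PAB iff its border actin fraction **exceeds** `f_thresh` and its
#' circularity **exceeds** `c_thresh` (both strict: a cell at exactly 0.50 /
#' 0.60 is not PAB).
#'
#' @param border_fraction Border actin fraction in \[0, 1\].
#' @param circularity Circularity in \[0, 1\].
#' @param thresholds A [pab_thresholds()].
#'
#' @return Logical.
#' @export
#' @examples
#' classify_pab(0.60, 0.80)  # TRUE
#' classify_pab(0.50, 0.60)  # FALSE: boundaries are strict
classify_pab <- function(border_fraction, circularity,
                         thresholds = pab_thresholds()) {
  check_fraction(border_fraction, "border_fraction")
  check_fraction(circularity, "circularity")
  border_fraction > thresholds$f_thresh & circularity > thresholds$c_thresh
}

#' Measure one cell image end to end
#'
#' Convenience wrapper: segment, measure shape, extract border band, compute
#' the border actin fraction, and classify.
#'
#' @param image An [intensity_image()].
#' @param thresholds A [pab_thresholds()].
#' @param cell_id,field_id Labels carried into the output row.
#' @param ... Passed to [segment_cell()].
#'
#' @return One-row tibble: `cell_id`, `field_id`, `area_um2`, `perimeter_um`,
#'   `circularity`, `border_fraction`, `is_pab`.
#' @export
measure_cell <- function(image, thresholds = pab_thresholds(),
                         cell_id = "cell", field_id = "field", ...) {
  mask <- segment_cell(image, ...)
  shape <- measure_shape(mask)
  band <- border_band(mask, thresholds$band_fraction)
  f <- border_actin_fraction(image, mask, band)
  tibble(
    cell_id = cell_id, field_id = field_id,
    area_um2 = shape$area_um2, perimeter_um = shape$perimeter_um,
    circularity = shape$circularity, border_fraction = f,
    is_pab = classify_pab(f, shape$circularity, thresholds)
  )
}

#' PAB rate per imaging field
#'
#' @param records Tibble of per-cell records with `field_id` and `is_pab`
#'   columns (as produced by [measure_cell()]).
#'
#' @return Tibble with `field_id`, `n_cells`, `pab_percent`.
#' @export
#' @examples
#' recs <- tibble::tibble(field_id = "f1", is_pab = c(TRUE, FALSE, FALSE,
#'   FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
#' pab_rate(recs)  # 20%
pab_rate <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("field_id", "is_pab") %in% names(records)))
  if (nrow(records) == 0L) {
    abort("No records.", class = "pabscope_validation_error")
  }
  records |>
    dplyr::group_by(.data$field_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      pab_percent = 100 * mean(.data$is_pab),
      .groups = "drop"
    )
}

#' Detect focal adhesions in a paxillin image
#'
#' Thresholds the image (Otsu on the raw pixels by default), labels connected
#' components, and keeps those whose area falls inside `size_range_um2`.
#'
#' @param image An [intensity_image()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param size_range_um2 Length-2 numeric, inclusive area range (um^2).
#' @param fixed_threshold Threshold when `threshold_method = "fixed"`.
#'
#' @return Tibble with one row per adhesion: `fa_id`, `centroid_row`,
#'   `centroid_col`, `area_um2`. Zero rows when none detected.
#' @export
detect_focal_adhesions <- function(image, threshold_method = c("otsu", "fixed"),
                                   size_range_um2 = c(0.1, 30),
                                   fixed_threshold = NULL) {
  stopifnot(inherits(image, "intensity_image"), length(size_range_um2) == 2L)
  threshold_method <- match.arg(threshold_method)
  px <- image$pixels
  thr <- switch(threshold_method,
    otsu = otsu_threshold(px),
    fixed = {
      check_nonneg_scalar(fixed_threshold, "fixed_threshold")
      fixed_threshold
    }
  )
  fg <- px > thr
  empty <- tibble(fa_id = integer(), centroid_row = numeric(),
                  centroid_col = numeric(), area_um2 = numeric())
  if (!any(fg)) return(empty)
  lab <- EBImage::bwlabel(fg)
  ids <- sort(unique(lab[lab > 0]))
  px_area <- image$pixel_size_um^2
  rows <- purrr::map(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    a <- nrow(idx) * px_area
    tibble(fa_id = as.integer(i), centroid_row = mean(idx[, 1]),
           centroid_col = mean(idx[, 2]), area_um2 = a)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$area_um2 >= size_range_um2[1],
                  .data$area_um2 <= size_range_um2[2])
  out$fa_id <- seq_len(nrow(out))
  out
}

# ---- shared image helpers ---------------------------------------------------

mask_matrix <- function(mask) {
  if (inherits(mask, "cell_mask")) return(mask$pixels)
  if (is.matrix(mask)) return(mask > 0)
  abort("Expected a cell_mask or logical matrix.",
        class = "pabscope_validation_error")
}

# Separable Gaussian blur with replicate padding (sigma in px).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(x, along_rows) {
    if (along_rows) x <- t(x)
    n <- ncol(x)
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    xp <- x[, idx, drop = FALSE]
    out <- matrix(0, nrow(x), n)
    for (j in seq_len(2L * r + 1L)) {
      out <- out + k[j] * xp[, j:(j + n - 1L), drop = FALSE]
    }
    if (along_rows) t(out) else out
  }
  blur_axis(blur_axis(m, FALSE), TRUE)
}

# Otsu threshold on the raw intensity scale.
otsu_threshold <- function(px) {
  rng <- range(px)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (px - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}
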