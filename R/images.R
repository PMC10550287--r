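#' Calibrated grayscale image
#'
#' A minimal container for a 2D fluorescence micrograph: a numeric matrix of
#' non-negative intensities plus the physical pixel size. Rows index image
#' rows (origin top-left), columns index image columns; all reported lengths
#' are micrometres via `pixel_size_um`.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um Positive scalar, physical size of one pixel edge (um).
#' @param channel Optional label for the stain/channel (e.g. "phalloidin").
#'
#' @return An `intensity_image` object.
#' @export
#' @examples
#' img <- intensity_image(matrix(runif(64), 8, 8), pixel_size_um = 0.3)
#' dim(img$pixels)
intensity_image <- function(pixels, pixel_size_um, channel = "gray") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "pabscope_validation_error")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be finite and non-negative.", class = "pabscope_validation_error")
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, channel = channel),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %d x %d px, %.4g um/px, channel '%s'\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel
  ))
  invisible(x)
}

#' @export
as_tibble.intensity_image <- function(x, ...) {
  px <- x$pixels
  tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    x_um = (rep(seq_len(ncol(px)), each = nrow(px)) - 0.5) * x$pixel_size_um,
    y_um = (rep(seq_len(nrow(px)), times = ncol(px)) - 0.5) * x$pixel_size_um,
    intensity = as.vector(px)
  )
}

#' Binary cell mask sharing image geometry
#'
#' @param pixels Logical (or 0/1 numeric) matrix; `TRUE` marks the cell.
#' @param pixel_size_um Positive scalar pixel size (um).
#' @param component_id Integer label of the connected component retained.
#'
#' @return A `cell_mask` object.
#' @export
cell_mask <- function(pixels, pixel_size_um, component_id = 1L) {
  if (is.numeric(pixels)) pixels <- pixels > 0
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    abort("`pixels` must be a logical matrix.", class = "pabscope_validation_error")
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         component_id = as.integer(component_id)),
    class = "cell_mask"
  )
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf(
    "<cell_mask> %d x %d px, %d foreground px (%.4g um/px)\n",
    nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$pixel_size_um
  ))
  invisible(x)
}

#' Read a grayscale TIFF as an intensity image
#'
#' @param path Path to a TIFF file (8/16-bit or float).
#' @param pixel_size_um Pixel size in micrometres.
#' @param channel Channel label.
#'
#' @return An [intensity_image()].
#' @export
read_image <- function(path, pixel_size_um, channel = "gray") {
  arr <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  intensity_image(unclass(as.matrix(arr)) * 1.0, pixel_size_um, channel)
}

#' Write an intensity image as 16-bit TIFF
#'
#' Intensities are scaled to the full 16-bit range by the image maximum
#' (a zero image is written as all-zero).
#'
#' @param image An [intensity_image()].
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- image$pixels
  mx <- max(px)
  scaled <- if (mx > 0) px / mx else px
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- internal validation helpers -------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar.", name),
          class = "pabscope_validation_error")
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a non-negative finite scalar.", name),
          class = "pabscope_validation_error")
  }
  invisible(x)
}

check_fraction <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in %s0, 1%s.", name,
                  if (open_lower) "(" else "[", if (open_upper) ")" else "]"),
          class = "pabscope_validation_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "pabscope_validation_error")
  }
  invisible(as.integer(x))
}
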