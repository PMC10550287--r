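#' Strain energy stored in the substrate under the cell
#'
#' `U = 1/2 * sum over in-mask nodes of (u . T) dA`, converted to joules
#' (`u` um -> m, `T` Pa, `dA` um^2 -> m^2), and normalized by the cell area
#' in um^2. The mask is resampled to the field grid by nearest-node lookup.
#'
#' @param u A [displacement_field()].
#' @param traction A [traction_field()] on the same grid.
#' @param mask A [cell_mask()] at image resolution, a logical matrix already
#'   on the field grid, or `NULL` to integrate over the whole field.
#'
#' @return One-row tibble: `strain_energy_j`, `cell_area_um2`,
#'   `normalized_energy_j_per_um2`.
#' @export
strain_energy <- function(u, traction, mask = NULL) {
  stopifnot(inherits(u, "displacement_field"),
            inherits(traction, "traction_field"))
  if (!all(dim(u$ux) == dim(traction$tx))) {
    abort("Displacement and traction grids differ.",
          class = "pabscope_validation_error")
  }
  node_mask <- mask_on_grid(mask, u)
  if (!any(node_mask)) {
    abort("Empty mask.", class = "pabscope_validation_error")
  }
  h_um <- field_spacing_um(u)
  dA_um2 <- h_um^2
  dens <- 0.5 * (u$ux * traction$tx + u$uy * traction$ty)  # um * Pa
  U <- sum(dens[node_mask]) * dA_um2 * 1e-18               # -> joules
  area <- sum(node_mask) * dA_um2
  tibble(strain_energy_j = U, cell_area_um2 = area,
         normalized_energy_j_per_um2 = U / area)
}

#' Residual energy fraction and QC flag
#'
#' Share of the total (positive-part) strain energy located outside the cell
#' footprint after dilating the mask by `margin_px` image pixels. Cells with
#' a residual fraction of 0.20 or more fail QC and are excluded.
#'
#' @param u A [displacement_field()].
#' @param traction Matching [traction_field()].
#' @param mask Cell footprint (see [strain_energy()]); required here.
#' @param margin_px Dilation margin in image pixels, default 10.
#'
#' @return One-row tibble: `residual_energy_fraction`, `passed_qc`.
#' @export
residual_energy_fraction <- function(u, traction, mask, margin_px = 10) {
  stopifnot(inherits(u, "displacement_field"),
            inherits(traction, "traction_field"))
  if (!all(dim(u$ux) == dim(traction$tx))) {
    abort("Displacement and traction grids differ.",
          class = "pabscope_validation_error")
  }
  node_mask <- mask_on_grid(mask, u)
  if (is.null(node_mask) || !any(node_mask)) {
    abort("Residual energy needs a non-empty cell mask.",
          class = "pabscope_validation_error")
  }
  margin_nodes <- ceiling(margin_px / u$grid_spacing_px)
  dilated <- dilate_mask(node_mask, margin_nodes)
  dens <- pmax(0.5 * (u$ux * traction$tx + u$uy * traction$ty), 0)
  total <- sum(dens)
  if (total <= 0) {
    abort("Total strain energy is zero; residual fraction undefined.",
          class = "pabscope_undefined_fraction")
  }
  frac <- sum(dens[!dilated]) / total
  frac <- min(max(frac, 0), 1)
  tibble(residual_energy_fraction = frac, passed_qc = frac < 0.20)
}

# Resample an image-resolution mask onto field nodes (nearest pixel).
mask_on_grid <- function(mask, field) {
  if (is.null(mask)) {
    return(matrix(TRUE, nrow(field$ux), ncol(field$ux)))
  }
  m <- mask_matrix(mask)
  if (all(dim(m) == dim(field$ux))) return(m)
  gs <- field$grid_spacing_px
  rows <- round((seq_len(nrow(field$ux)) - 0.5) * gs + field$origin_px[1])
  cols <- round((seq_len(ncol(field$ux)) - 0.5) * gs + field$origin_px[2])
  rows <- pmin(pmax(rows, 1), nrow(m))
  cols <- pmin(pmax(cols, 1), ncol(m))
  m[rows, cols, drop = FALSE]
}

dilate_mask <- function(m, d) {
  if (d <= 0 || all(m)) return(m)
  dist_to_mask <- EBImage::distmap((!m) * 1.0)
  m | (matrix(dist_to_mask, nrow(m), ncol(m)) <= d)
}

#' Full TFM result for one cell
#'
#' Composes [strain_energy()] and [residual_energy_fraction()] into the
#' per-cell readout used in batch reports.
#'
#' @inheritParams residual_energy_fraction
#' @return One-row tibble: energies, residual fraction, `passed_qc`,
#'   `lambda_used`.
#' @export
tfm_result <- function(u, traction, mask, margin_px = 10) {
  en <- strain_energy(u, traction, mask)
  qc <- residual_energy_fraction(u, traction, mask, margin_px)
  dplyr::bind_cols(en, qc) |>
    dplyr::mutate(lambda_used = traction$lambda_used)
}
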