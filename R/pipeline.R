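#' Run configuration
#'
#' Validated bag of pipeline parameters; round-trips losslessly to YAML via
#' [write_run_config()] / [read_run_config()]. Defaults are the assay
#' constants used throughout the package: PAB thresholds 0.50 / 0.60 with a 0.20 border band, a 16 kPa
#' shear-modulus substrate with `nu = 0.5`, a 16 px matching window,
#' `lambda = 9.34e-9`, a 10 px residual-energy margin, and the
#' 0.00664 N/m / 1.75 um AFM cantilever with `mu = 0.5`.
#'
#' @param pixel_size_um Image pixel size (um).
#' @param f_thresh,c_thresh,band_fraction PAB thresholds, see
#'   [pab_thresholds()].
#' @param shear_modulus_pa,poisson_ratio Substrate, see [substrate_model()].
#' @param window_px,grid_spacing_px,lambda,margin_px TFM parameters.
#' @param k_n_per_m,tip_radius_um,mu AFM constants.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory or `NULL`.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(pixel_size_um = 0.4,
                       f_thresh = 0.50, c_thresh = 0.60, band_fraction = 0.20,
                       shear_modulus_pa = 16000, poisson_ratio = 0.5,
                       window_px = 16L, grid_spacing_px = 8L,
                       lambda = 9.34e-9, margin_px = 10,
                       k_n_per_m = 0.00664, tip_radius_um = 1.75, mu = 0.5,
                       seed = 1L, out_dir = NULL) {
  cfg <- list(
    pixel_size_um = pixel_size_um,
    f_thresh = f_thresh, c_thresh = c_thresh, band_fraction = band_fraction,
    shear_modulus_pa = shear_modulus_pa, poisson_ratio = poisson_ratio,
    window_px = as.integer(window_px),
    grid_spacing_px = as.integer(grid_spacing_px),
    lambda = lambda, margin_px = margin_px,
    k_n_per_m = k_n_per_m, tip_radius_um = tip_radius_um, mu = mu,
    seed = as.integer(seed), out_dir = out_dir
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  check_positive_scalar(cfg$pixel_size_um, "pixel_size_um")
  pab_thresholds(cfg$f_thresh, cfg$c_thresh, cfg$band_fraction)
  substrate_model(shear_modulus_pa = cfg$shear_modulus_pa,
                  poisson_ratio = cfg$poisson_ratio)
  check_count(cfg$window_px, "window_px", min = 8L)
  check_count(cfg$grid_spacing_px, "grid_spacing_px")
  check_nonneg_scalar(cfg$lambda, "lambda")
  check_nonneg_scalar(cfg$margin_px, "margin_px")
  check_positive_scalar(cfg$k_n_per_m, "k_n_per_m")
  check_positive_scalar(cfg$tip_radius_um, "tip_radius_um")
  check_fraction(cfg$mu, "mu", open_upper = TRUE)
  invisible(cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the PAB morphometry study over a batch of images
#'
#' Segments, measures, and classifies every cell image, aggregates PAB rates
#' per field, and compares conditions when labels are present. Cells that
#' fail (unreadable image, no cell found) are logged as exclusions with their
#' reason; the run continues, and fails only when nothing is analyzable.
#'
#' @param manifest Tibble with one row per cell: `cell_id`, `field_id`,
#'   optional `condition`, and either an `image` list-column of
#'   [intensity_image()]s or a `path` column of TIFF files.
#' @param config A [run_config()].
#'
#' @return A `run_report` list: `per_cell`, `per_field`, `comparison`,
#'   `exclusions`, `config`, and (when `out_dir` is set) `files` and `hash`.
#' @export
run_pab_study <- function(manifest, config = run_config()) {
  stopifnot(is.data.frame(manifest),
            all(c("cell_id", "field_id") %in% names(manifest)))
  if (nrow(manifest) == 0L) {
    abort("Empty manifest.", class = "pabscope_run_error")
  }
  thr <- pab_thresholds(config$f_thresh, config$c_thresh, config$band_fraction)
  rows <- vector("list", nrow(manifest))
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      img <- if ("image" %in% names(manifest)) {
        manifest$image[[i]]
      } else {
        read_image(manifest$path[i], config$pixel_size_um)
      }
      measure_cell(img, thresholds = thr,
                   cell_id = manifest$cell_id[i],
                   field_id = manifest$field_id[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- tibble(
        cell_id = manifest$cell_id[i], stage = "morphometry",
        reason = conditionMessage(res)
      )
    } else {
      if ("condition" %in% names(manifest)) {
        res$condition <- manifest$condition[i]
      }
      rows[[i]] <- res
    }
  }
  per_cell <- dplyr::bind_rows(rows)
  if (nrow(per_cell) == 0L) {
    abort("No readable images in the manifest.", class = "pabscope_run_error")
  }
  per_field <- pab_rate(per_cell)
  comparison <- NULL
  if ("condition" %in% names(per_cell) &&
      dplyr::n_distinct(per_cell$condition) >= 2L) {
    comparison <- group_compare(per_cell, "border_fraction", "condition")
  }
  finish_report(
    list(per_cell = per_cell, per_field = per_field, comparison = comparison,
         exclusions = dplyr::bind_rows(excl), config = config),
    stage = "pab"
  )
}

#' Run the TFM study over a batch of scenes
#'
#' Each manifest row is one cell: either precomputed displacement fields
#' (`u` list-column) or bead image pairs (`reference`, `deformed`
#' list-columns) that are registered and matched first. Tractions are
#' recovered by [fttc()], strain energy summed under the `mask`, and the
#' residual-energy QC filter applied; excluded cells are listed with their
#' triggering rule.
#'
#' @param manifest Tibble with `cell_id`, a `mask` list-column, and either a
#'   `u` list-column of [displacement_field()]s or `reference`/`deformed`
#'   list-columns of [intensity_image()]s.
#' @param config A [run_config()].
#'
#' @return A `run_report` with `per_cell` (retained cells), `exclusions`,
#'   `config`.
#' @export
run_tfm_study <- function(manifest, config = run_config()) {
  stopifnot(is.data.frame(manifest), "cell_id" %in% names(manifest),
            "mask" %in% names(manifest))
  if (nrow(manifest) == 0L) {
    abort("Empty manifest.", class = "pabscope_run_error")
  }
  substrate <- substrate_model(shear_modulus_pa = config$shear_modulus_pa,
                               poisson_ratio = config$poisson_ratio)
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      u <- if ("u" %in% names(manifest)) {
        manifest$u[[i]]
      } else {
        reg <- register_reference(manifest$reference[[i]],
                                  manifest$deformed[[i]])
        estimate_displacements(reg$aligned, manifest$deformed[[i]],
                               window_px = config$window_px,
                               grid_spacing_px = config$grid_spacing_px)
      }
      tr <- fttc(u, substrate, lambda = config$lambda)
      tfm_result(u, tr, manifest$mask[[i]], margin_px = config$margin_px)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- tibble(
        cell_id = manifest$cell_id[i], stage = "tfm",
        reason = conditionMessage(res)
      )
      next
    }
    res$cell_id <- manifest$cell_id[i]
    if (!res$passed_qc) {
      excl[[length(excl) + 1L]] <- tibble(
        cell_id = manifest$cell_id[i], stage = "tfm_qc",
        reason = sprintf("residual_energy >= 0.20 (%.3f)",
                         res$residual_energy_fraction)
      )
      next
    }
    rows[[length(rows) + 1L]] <- res
  }
  per_cell <- dplyr::bind_rows(rows)
  finish_report(
    list(per_cell = per_cell, exclusions = dplyr::bind_rows(excl),
         config = config),
    stage = "tfm"
  )
}

#' Run the AFM stiffness study over a batch of force curves
#'
#' Fits every curve with [fit_force_curve()]; fit failures are logged and
#' excluded. When condition labels are present the fitted moduli are compared
#' across groups.
#'
#' @param manifest Tibble with `cell_id`, optional `condition`, and a
#'   `curve` list-column of [force_curve()]s.
#' @param config A [run_config()].
#'
#' @return A `run_report` with `per_cell` fits, `comparison`, `exclusions`.
#' @export
run_afm_study <- function(manifest, config = run_config()) {
  stopifnot(is.data.frame(manifest), "cell_id" %in% names(manifest),
            "curve" %in% names(manifest))
  if (nrow(manifest) == 0L) {
    abort("Empty manifest.", class = "pabscope_run_error")
  }
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      glance(fit_force_curve(manifest$curve[[i]], mu = config$mu)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- tibble(
        cell_id = manifest$cell_id[i], stage = "afm",
        reason = conditionMessage(res)
      )
      next
    }
    res$cell_id <- manifest$cell_id[i]
    if ("condition" %in% names(manifest)) {
      res$condition <- manifest$condition[i]
    }
    rows[[length(rows) + 1L]] <- res
  }
  per_cell <- dplyr::bind_rows(rows)
  comparison <- NULL
  if (nrow(per_cell) > 0L && "condition" %in% names(per_cell) &&
      dplyr::n_distinct(per_cell$condition) >= 2L) {
    comparison <- group_compare(per_cell, "modulus_pa", "condition")
  }
  finish_report(
    list(per_cell = per_cell, comparison = comparison,
         exclusions = dplyr::bind_rows(excl), config = config),
    stage = "afm"
  )
}

# Write report tables (CSV + config YAML + summary JSON) when out_dir is set,
# and hash everything written so identical reruns can be checked bytewise.
finish_report <- function(report, stage) {
  report$stage <- stage
  cfg <- report$config
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    wr <- function(df, name) {
      if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
      p <- file.path(cfg$out_dir, sprintf("%s_%s.csv", stage, name))
      readr::write_csv(df, p)
      files <<- c(files, p)
    }
    wr(report$per_cell, "per_cell")
    wr(report$per_field, "per_field")
    wr(report$comparison, "comparison")
    wr(report$exclusions, "exclusions")
    pc <- file.path(cfg$out_dir, sprintf("%s_config.yaml", stage))
    write_run_config(cfg, pc)
    files <- c(files, pc)
    report$files <- files
    report$hash <- unname(tools::md5sum(sort(files)))
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  n_in <- nrow(x$per_cell %||% tibble()) + nrow(x$exclusions %||% tibble())
  cat(sprintf("<run_report> stage '%s': %d analyzed, %d excluded\n",
              x$stage, nrow(x$per_cell %||% tibble()),
              nrow(x$exclusions %||% tibble())))
  if (!is.null(x$comparison)) {
    cat(sprintf("  group comparison: %s, statistic %.3g, p = %.3g\n",
                x$comparison$design, x$comparison$statistic,
                x$comparison$p_value))
  }
  invisible(x)
}
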