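#' Per-track migration statistics
#'
#' Computes, for each track, the mean speed (total path length over elapsed
#' time — the track-plugin convention, not a frame-wise average), the path
#' length, net displacement, and the directionality index
#' (net displacement / path length; 1 for a perfectly straight path).
#' Missing frames are tolerated: steps are taken between available
#' consecutive points.
#'
#' @param tracks Tibble with columns `track_id`, `t_min`, `x_um`, `y_um`.
#'
#' @return Tibble with one row per track: `track_id`, `n_points`,
#'   `path_length_um`, `net_displacement_um`, `mean_speed_um_min`,
#'   `directionality`. `directionality` is `NA` for zero-path tracks.
#' @export
#' @examples
#' tr <- tibble::tibble(track_id = "a", t_min = c(0, 10, 20),
#'                      x_um = c(0, 5, 10), y_um = 0)
#' track_stats(tr)
track_stats <- function(tracks) {
  check_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(~ one_track_stats(.x)) |>
    dplyr::ungroup()
}

one_track_stats <- function(tr) {
  tr <- dplyr::arrange(tr, .data$t_min)
  if (nrow(tr) < 2L) {
    abort("Each track needs at least 2 points.",
          class = "pabscope_validation_error")
  }
  if (any(diff(tr$t_min) <= 0)) {
    abort("Track times must be strictly increasing.",
          class = "pabscope_validation_error")
  }
  steps <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  path <- sum(steps)
  net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
              (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
  elapsed <- tr$t_min[nrow(tr)] - tr$t_min[1]
  tibble(
    n_points = nrow(tr),
    path_length_um = path,
    net_displacement_um = net,
    mean_speed_um_min = path / elapsed,
    directionality = if (path > 0) net / path else NA_real_
  )
}

#' Mean speed of a single track
#'
#' @param track Tibble with `t_min`, `x_um`, `y_um` (single track).
#' @return Scalar mean speed (um/min): path length over elapsed time.
#' @export
track_speed <- function(track) {
  stopifnot(is.data.frame(track))
  one_track_stats(track)$mean_speed_um_min
}

#' Directionality index of a single track
#'
#' @param track Tibble with `t_min`, `x_um`, `y_um` (single track).
#' @return Net displacement over path length, in \[0, 1\].
#' @export
directionality <- function(track) {
  s <- one_track_stats(track)
  if (is.na(s$directionality)) {
    abort("Zero path length; directionality undefined.",
          class = "pabscope_undefined_directionality")
  }
  s$directionality
}

#' Wind-rose sector counts of net-displacement angles
#'
#' Each track contributes one count: the angle of its net displacement vector,
#' binned into half-open sectors `[theta, theta + 2*pi/n)` with sector 1
#' starting at the +x axis and proceeding counter-clockwise. Tracks with zero
#' net displacement cannot be binned and are reported separately.
#'
#' @param tracks Tibble with `track_id`, `t_min`, `x_um`, `y_um`.
#' @param n_sectors Number of angular sectors (>= 2), default 16.
#'
#' @return A list with `sectors` (tibble: `sector`, `theta_start_rad`, `count`)
#'   and `n_unbinnable` (tracks with zero net displacement).
#' @export
windrose <- function(tracks, n_sectors = 16) {
  check_tracks(tracks)
  n_sectors <- check_count(n_sectors, "n_sectors", min = 2L)
  ends <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::summarise(
      dx = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
      dy = dplyr::last(.data$y_um) - dplyr::first(.data$y_um),
      .groups = "drop"
    )
  movers <- ends |> dplyr::filter(.data$dx != 0 | .data$dy != 0)
  ang <- atan2(movers$dy, movers$dx) %% (2 * pi)
  width <- 2 * pi / n_sectors
  sector <- pmin(floor(ang / width), n_sectors - 1L) + 1L
  counts <- tabulate(sector, nbins = n_sectors)
  list(
    sectors = tibble(
      sector = seq_len(n_sectors),
      theta_start_rad = (seq_len(n_sectors) - 1L) * width,
      count = counts
    ),
    n_unbinnable = nrow(ends) - nrow(movers)
  )
}

#' Calcium fold-change trace
#'
#' Normalizes a raw intensity series to its first frame, so the trace starts
#' at exactly 1. Ratios are invariant to multiplicative rescaling of the raw
#' intensities.
#'
#' @param trace Tibble with columns `frame` and `intensity`, or a bare numeric
#'   vector of intensities.
#'
#' @return Tibble with `frame`, `intensity`, `fold_change`.
#' @export
#' @examples
#' fold_change_trace(c(100, 150, 200))$fold_change  # 1.0 1.5 2.0
fold_change_trace <- function(trace) {
  if (is.numeric(trace)) {
    trace <- tibble(frame = seq_along(trace), intensity = as.numeric(trace))
  }
  stopifnot(is.data.frame(trace),
            all(c("frame", "intensity") %in% names(trace)))
  trace <- dplyr::arrange(trace, .data$frame)
  first <- trace$intensity[1]
  if (!is.finite(first) || first <= 0) {
    abort("First-frame intensity must be positive.",
          class = "pabscope_validation_error")
  }
  dplyr::mutate(trace, fold_change = .data$intensity / first)
}

#' Two-group t test or one-way ANOVA
#'
#' The group statistics used for this kind of assay: an unpaired two-tailed Student's t test
#' (equal variances) for two groups, a one-way ANOVA F test for more. The
#' degenerate case of zero variance everywhere with equal group means returns
#' statistic 0 and p = 1.
#'
#' @param data Data frame with a numeric value column and a grouping column.
#' @param value,group Column names (strings) of values and condition labels.
#' @param design `"auto"` picks t test for 2 groups, ANOVA for more; may be
#'   forced to `"two_group"` or `"multi_group"`.
#'
#' @return One-row tibble: `design`, `statistic`, `p_value`, `df1`, `df2`.
#' @export
#' @examples
#' d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 7),
#'                     g = rep(c("a", "b"), each = 3))
#' group_compare(d, "v", "g")
group_compare <- function(data, value = "value", group = "group",
                          design = c("auto", "two_group", "multi_group")) {
  design <- match.arg(design)
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  v <- data[[value]]
  g <- factor(data[[group]])
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("Need >= 2 groups with >= 2 values each.",
          class = "pabscope_validation_error")
  }
  if (design == "auto") {
    design <- if (length(counts) == 2L) "two_group" else "multi_group"
  }
  if (design == "two_group" && length(counts) != 2L) {
    abort("two_group design requires exactly 2 groups.",
          class = "pabscope_validation_error")
  }
  means <- tapply(v, g, mean)
  within_var <- tapply(v, g, var)
  if (all(within_var == 0) && diff(range(means)) == 0) {
    return(tibble(design = design, statistic = 0, p_value = 1,
                  df1 = NA_real_, df2 = NA_real_))
  }
  if (design == "two_group") {
    tt <- stats::t.test(v ~ g, var.equal = TRUE)
    tibble(design = design, statistic = unname(tt$statistic),
           p_value = tt$p.value, df1 = unname(tt$parameter), df2 = NA_real_)
  } else {
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    tibble(design = design, statistic = s[["F value"]][1],
           p_value = s[["Pr(>F)"]][1],
           df1 = s[["Df"]][1], df2 = s[["Df"]][2])
  }
}

check_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks))
  need <- c("track_id", "t_min", "x_um", "y_um")
  if (!all(need %in% names(tracks))) {
    abort(sprintf("Tracks need columns: %s.", paste(need, collapse = ", ")),
          class = "pabscope_validation_error")
  }
  invisible(tracks)
}

#' Read / write track tables
#'
#' CSV layout: `track_id, frame, t_min, x_um, y_um`.
#'
#' @param path File path.
#' @return A tibble of tracks.
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_tracks
#' @param tracks Track tibble.
#' @export
write_tracks <- function(tracks, path) {
  check_tracks(tracks)
  readr::write_csv(tracks, path)
  invisible(path)
}
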