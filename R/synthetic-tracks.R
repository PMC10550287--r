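#' Specification for simulated migration tracks
#'
#' Persistent random walks: the heading turns by a wrapped-normal angle each
#' step, with the turning-angle spread mapped monotonically from
#' `persistence` (1 = collinear steps, 0 = isotropic directions). Step
#' lengths are Rayleigh-distributed with mean `mean_speed_um_min * dt_min`,
#' so the expected per-track mean speed equals `mean_speed_um_min`.
#'
#' @param n_tracks Number of tracks.
#' @param mean_speed_um_min Target mean speed (um/min).
#' @param persistence Directional persistence in \[0, 1\].
#' @param dt_min Frame interval (min).
#' @param n_steps Steps per track (each track has `n_steps + 1` points).
#' @param seed Integer seed.
#'
#' @return A `track_sim_spec` list.
#' @export
track_sim_spec <- function(n_tracks = 30L, mean_speed_um_min = 0.5,
                           persistence = 0.5, dt_min = 10, n_steps = 60L,
                           seed = 1L) {
  n_tracks <- check_count(n_tracks, "n_tracks")
  check_positive_scalar(mean_speed_um_min, "mean_speed_um_min")
  check_fraction(persistence, "persistence")
  check_positive_scalar(dt_min, "dt_min")
  n_steps <- check_count(n_steps, "n_steps")
  structure(
    list(n_tracks = n_tracks, mean_speed_um_min = mean_speed_um_min,
         persistence = persistence, dt_min = dt_min, n_steps = n_steps,
         seed = as.integer(seed)),
    class = "track_sim_spec"
  )
}

#' Simulate persistent-random-walk migration tracks
#'
#' @param spec A [track_sim_spec()].
#'
#' @return Tibble with columns `track_id`, `frame`, `t_min`, `x_um`, `y_um`.
#' @export
#' @examples
#' tr <- make_tracks(track_sim_spec(n_tracks = 5, seed = 3))
#' track_stats(tr)
make_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  mean_step <- spec$mean_speed_um_min * spec$dt_min
  rayleigh_sigma <- mean_step / sqrt(pi / 2)
  # wrapped-normal turning-angle sd: 0 at persistence 1, ~uniform at 0
  turn_sd <- if (spec$persistence >= 1) 0 else tan(pi / 2 * (1 - spec$persistence))

  purrr::map_dfr(seq_len(spec$n_tracks), function(i) {
    set.seed(derive_seed(spec$seed, i))
    n <- spec$n_steps
    if (spec$persistence <= 0) {
      theta <- runif(n, 0, 2 * pi)
    } else {
      theta0 <- runif(1, 0, 2 * pi)
      turns <- if (turn_sd == 0) rep(0, n) else rnorm(n, sd = turn_sd)
      theta <- (theta0 + cumsum(c(0, turns[-1]))) %% (2 * pi)
    }
    if (spec$persistence >= 1) {
      # collinear: identical step lengths too, so directionality is exactly 1
      steps <- rep(mean_step, n)
    } else {
      steps <- rayleigh_sigma * sqrt(-2 * log(runif(n)))
    }
    tibble(
      track_id = sprintf("track_%04d", i),
      frame = 0:n,
      t_min = (0:n) * spec$dt_min,
      x_um = cumsum(c(0, steps * cos(theta))),
      y_um = cumsum(c(0, steps * sin(theta)))
    )
  })
}
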