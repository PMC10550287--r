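#' Simulate a baseline-then-peak calcium transient
#'
#' Raw Fluo-4-like intensities: flat baseline until `onset_frame`, then an
#' instantaneous rise to `peak_fold * baseline` decaying exponentially back
#' toward baseline with time constant `decay_frames`. The noiseless
#' fold-change trace (normalized to frame 1) therefore starts at 1 and peaks
#' at exactly `peak_fold`.
#'
#' @param baseline Baseline intensity (> 0, AU).
#' @param peak_fold Peak fold change (>= 1).
#' @param onset_frame Frame of the stimulus response (2 <= onset < n_frames).
#' @param decay_frames Exponential decay constant (frames).
#' @param n_frames Number of frames.
#' @param noise_sd Gaussian noise sd (AU).
#' @param seed Integer seed.
#'
#' @return Tibble with `frame` and `intensity`.
#' @export
#' @examples
#' tr <- make_calcium_trace(peak_fold = 2, onset_frame = 5, n_frames = 25)
#' max(fold_change_trace(tr)$fold_change)
make_calcium_trace <- function(baseline = 100, peak_fold = 2,
                               onset_frame = 3L, decay_frames = 8,
                               n_frames = 25L, noise_sd = 0, seed = 1L) {
  check_positive_scalar(baseline, "baseline")
  if (peak_fold < 1) {
    abort("`peak_fold` must be >= 1.", class = "pabscope_validation_error")
  }
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  onset_frame <- check_count(onset_frame, "onset_frame", min = 2L)
  if (onset_frame >= n_frames) {
    abort("`onset_frame` must be < n_frames.",
          class = "pabscope_validation_error")
  }
  check_positive_scalar(decay_frames, "decay_frames")
  check_nonneg_scalar(noise_sd, "noise_sd")

  frame <- seq_len(n_frames)
  intensity <- rep(baseline, n_frames)
  post <- frame >= onset_frame
  intensity[post] <- baseline *
    (1 + (peak_fold - 1) * exp(-(frame[post] - onset_frame) / decay_frames))
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    intensity <- pmax(intensity + rnorm(n_frames, sd = noise_sd), 0)
  }
  tibble(frame = frame, intensity = intensity)
}
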