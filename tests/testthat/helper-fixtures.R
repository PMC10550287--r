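# Shared fixtures, all generated in code.

# Mixed-phenotype phantom cohort with ground-truth PAB labels.
phantom_cohort <- function(n, prop_pab, seed, field_id = "field_1",
                           noise_sd = 4) {
  n_pab <- round(n * prop_pab)
  labels <- rep(c(TRUE, FALSE), c(n_pab, n - n_pab))
  specs <- lapply(seq_len(n), function(i) {
    if (labels[i]) {
      phantom_cell_spec("pab", ring_intensity_share = 0.75,
                        noise_sd = noise_sd, seed = seed + i)
    } else {
      phantom_cell_spec("polarized", axis_ratio = 3,
                        equivalent_radius_um = 16,
                        ring_intensity_share = 0.25,
                        noise_sd = noise_sd, seed = seed + i)
    }
  })
  tibble::tibble(
    cell_id = sprintf("cell_%03d", seq_len(n)),
    field_id = field_id,
    is_pab_true = labels,
    image = lapply(specs, function(s) make_cell_phantom(s)$image)
  )
}

# The standard contractile two-spot scene used across TFM tests.
two_spot_scene <- function(seed = 1, noise_sd_um = 0) {
  make_traction_scene(traction_scene_spec(seed = seed,
                                          noise_sd_um = noise_sd_um))
}

# Mask covering the central region of the standard 128 x 128 scene.
two_spot_mask <- function(scene, half_width_nodes = 40) {
  nr <- nrow(scene$traction$tx)
  nc <- ncol(scene$traction$tx)
  m <- matrix(FALSE, nr, nc)
  rr <- (nr / 2 - half_width_nodes):(nr / 2 + half_width_nodes)
  cc <- (nc / 2 - half_width_nodes):(nc / 2 + half_width_nodes)
  m[rr, cc] <- TRUE
  m
}

rel_l2 <- function(a_x, a_y, b_x, b_y) {
  sqrt(sum((a_x - b_x)^2 + (a_y - b_y)^2) / sum(b_x^2 + b_y^2))
}

simple_track <- function(x, y, dt = 10, id = "t1") {
  tibble::tibble(track_id = id, t_min = seq_along(x) * dt - dt,
                 x_um = x, y_um = y)
}
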