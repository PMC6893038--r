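# Shared fixtures and independent oracles.

# Brute-force interaural transform: build the unit vector, rotate the frame
# with an explicit rotation matrix so the interaural (y) axis becomes the
# pole, and read generic spherical coordinates off the rotated vector.
oracle_interaural <- function(azimuth, elevation) {
  th <- azimuth * pi / 180
  ph <- elevation * pi / 180
  v <- rbind(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
  # rotation about the x axis by +90 deg: y -> z, z -> -y in the new frame
  R <- matrix(c(
    1, 0, 0,
    0, 0, -1,
    0, 1, 0
  ), nrow = 3, byrow = TRUE)
  w <- R %*% v
  # colatitude from the new pole gives the lateral angle; the new-frame
  # azimuth runs opposite to the polar-angle convention
  lateral <- 90 - acos(pmin(1, pmax(-1, w[3, ]))) * 180 / pi
  polar <- atan2(-w[2, ], w[1, ]) * 180 / pi
  list(lateral = lateral, polar = polar)
}

random_directions <- function(n) {
  # uniform over the full sphere
  z <- stats::runif(n, -1, 1)
  az <- stats::runif(n, 0, 360)
  tibble::tibble(azimuth = az, elevation = asin(z) * 180 / pi)
}

# A listener profile row with every bias switched off (always responds at
# the target, apart from whatever parameters the caller overrides).
make_profile <- function(group = "non_gamified", p_fb0 = 0, lateral_bias0 = 0,
                         elevation_bias0 = 0, noise_kappa0 = Inf, b_gen = 0,
                         floor_fraction = 0.5, polar_transfer = 0.45,
                         completed_blocks = 0L) {
  tibble::tibble(
    participant_id = "P01", group = group, p_fb0 = p_fb0,
    lateral_bias0 = lateral_bias0, elevation_bias0 = elevation_bias0,
    noise_kappa0 = noise_kappa0, b_gen = b_gen,
    floor_fraction = floor_fraction, polar_transfer = polar_transfer,
    completed_blocks = completed_blocks
  )
}

# Minimal valid trial log around explicit target/response pairs.
make_toy_log <- function(target_az, target_el, response_az, response_el,
                         participant_id = "P01", group = "non_gamified",
                         block_index = 1L, day = 1L, block_type = "test",
                         hrtf = "trained", completed = 0L) {
  n <- length(target_az)
  tibble::tibble(
    participant_id = rep_len(participant_id, n),
    group = rep_len(group, n),
    day = rep_len(day, n),
    block_index = rep_len(block_index, n),
    block_type = rep_len(block_type, n),
    trial_index = seq_len(n),
    hrtf = rep_len(hrtf, n),
    target_az = target_az, target_el = target_el,
    response_az = response_az, response_el = response_el,
    completed_training_blocks = rep_len(completed, n),
    level = NA_integer_, hit = NA
  )
}

# Small cohort configuration for fast end-to-end runs.
small_listener_config <- function(...) {
  listener_config(
    group_sizes = c(
      control = 3, non_gamified = 3, gamified = 3, active_gamified = 3
    ),
    ...
  )
}
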