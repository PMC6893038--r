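#' Listener-model configuration
#'
#' Parameters of the phenomenological virtual-listener model and the cohort
#' generator. The model reproduces the statistical signatures typical of
#' naive listeners localizing virtual sounds spatialized with
#' non-individualized HRTFs: a front-back confusion probability around 40%,
#' a tendency to respond more laterally than the target (about +9 degrees),
#' a tendency to respond below the target (about -15 degrees), and isotropic
#' angular response noise. Training shrinks all of these along a shared
#' exponential adaptation state
#' `s = floor_fraction + (1 - floor_fraction) * exp(-b * completed_blocks)`,
#' with group-specific rates `b` seeded from the group-level learning-curve
#' fits of the study this package models (0.270, 0.320 and 0.710 per
#' training block for the non-gamified, gamified and active-gamified
#' variants; 0 for the untrained control).
#'
#' @param p_fb0 Initial front-back confusion probability.
#' @param lateral_bias0 Initial lateral overshoot, degrees (added to the
#'   magnitude of the response lateral angle).
#' @param elevation_bias0 Initial elevation bias, degrees (negative = below
#'   the target).
#' @param noise_kappa0 Initial concentration of the isotropic
#'   von Mises-Fisher response noise (larger = less noisy; the angular
#'   spread is roughly `1/sqrt(kappa)` radians). Training divides the
#'   effective concentration by the adaptation state `s`.
#' @param floor_fraction Residual fraction of each bias that never adapts;
#'   sets the asymptote of the learning curve.
#' @param learn_rates Named per-group adaptation rates per training block.
#' @param polar_transfer Fraction of the *elevation/polar* adaptation that
#'   transfers to the untrained HRTF condition (the front-back, lateral and
#'   noise components transfer fully). Values below 1 leave polar-angle
#'   judgements for the untrained set partially unadapted.
#' @param jitter_sd Per-participant between-subject variation: standard
#'   deviations for `p_fb` (probability), `lateral_bias` and
#'   `elevation_bias` (degrees), `noise_log` (lognormal sd of kappa),
#'   `b_rel` (relative sd of the learning rate) and `floor` (fraction). Set
#'   all to 0 for identical listeners within a group.
#' @param group_sizes Named participant counts.
#' @return A list of class `listener_config`.
#' @export
listener_config <- function(p_fb0 = 0.40,
                            lateral_bias0 = 9,
                            elevation_bias0 = -15,
                            noise_kappa0 = 10,
                            floor_fraction = 0.55,
                            learn_rates = c(
                              control = 0, non_gamified = 0.270,
                              gamified = 0.320, active_gamified = 0.710
                            ),
                            polar_transfer = 0.45,
                            jitter_sd = list(
                              p_fb = 0.08, lateral_bias = 3,
                              elevation_bias = 4, noise_log = 0.25,
                              b_rel = 0.2, floor = 0.05
                            ),
                            group_sizes = c(
                              control = 9, non_gamified = 9,
                              gamified = 7, active_gamified = 11
                            )) {
  stopifnot(
    p_fb0 >= 0, p_fb0 <= 1,
    noise_kappa0 > 0,
    floor_fraction > 0, floor_fraction < 1,
    polar_transfer >= 0, polar_transfer <= 1,
    all(learn_rates >= 0)
  )
  structure(
    list(
      p_fb0 = p_fb0, lateral_bias0 = lateral_bias0,
      elevation_bias0 = elevation_bias0, noise_kappa0 = noise_kappa0,
      floor_fraction = floor_fraction, learn_rates = learn_rates,
      polar_transfer = polar_transfer, jitter_sd = jitter_sd,
      group_sizes = group_sizes
    ),
    class = "listener_config"
  )
}

#' Generate a cohort of virtual listeners
#'
#' Creates one profile per participant with group sizes from the
#' configuration (defaults: control 9, non-gamified 9, gamified 7,
#' active-gamified 11) and per-participant parameter jitter around the
#' group-level defaults, emulating the large between-subject variability
#' such studies observe. Control listeners get a learning rate of exactly 0.
#'
#' @param config A [listener_config()].
#' @param seed Optional integer seed; when `NULL` the current R random
#'   number stream is used.
#' @return A tibble with one row per participant: `participant_id`, `group`,
#'   the per-participant model parameters, and `completed_blocks = 0`.
#' @examples
#' make_cohort(seed = 1)
#' @export
make_cohort <- function(config = listener_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- config$group_sizes
  group <- rep(names(sizes), times = sizes)
  n <- length(group)
  js <- config$jitter_sd
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  b0 <- unname(config$learn_rates[group])
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    group = group,
    p_fb0 = clamp(stats::rnorm(n, config$p_fb0, js$p_fb), 0.02, 0.98),
    lateral_bias0 = pmax(0, stats::rnorm(n, config$lateral_bias0, js$lateral_bias)),
    elevation_bias0 = stats::rnorm(n, config$elevation_bias0, js$elevation_bias),
    noise_kappa0 = config$noise_kappa0 * exp(stats::rnorm(n, 0, js$noise_log)),
    b_gen = ifelse(group == "control", 0,
      pmax(0, stats::rnorm(n, b0, js$b_rel * b0))
    ),
    floor_fraction = clamp(stats::rnorm(n, config$floor_fraction, js$floor), 0.2, 0.9),
    polar_transfer = config$polar_transfer,
    completed_blocks = 0L
  )
}

#' Adaptation state of a listener
#'
#' `s = floor_fraction + (1 - floor_fraction) * exp(-b * blocks)`: 1 for a
#' naive listener, decaying towards the non-adapting floor with completed
#' training blocks. All bias components scale with `s`.
#'
#' @param profile A single cohort row.
#' @param blocks Completed training blocks; defaults to the profile's
#'   counter.
#' @return The scalar adaptation state in `(0, 1]`.
#' @export
adaptation_state <- function(profile, blocks = profile$completed_blocks) {
  f <- profile$floor_fraction
  f + (1 - f) * exp(-profile$b_gen * blocks)
}

#' Record one completed training block
#'
#' Increments the listener's completed-block counter, advancing adaptation.
#' Adaptation changes only through this counter - there is no latent change
#' between sessions. Calling it on a control-group profile warns and leaves
#' the profile unchanged.
#'
#' @param profile A single cohort row.
#' @return The updated profile.
#' @export
advance_training <- function(profile) {
  if (identical(as.character(profile$group), "control")) {
    warning("advance_training() called on a control profile; ignored")
    return(profile)
  }
  profile$completed_blocks <- profile$completed_blocks + 1L
  profile
}

# One von Mises-Fisher draw about each (azimuth, elevation) direction with
# per-row concentration kappa. Inversion sampling of cos(deviation).
.rvmf_about <- function(azimuth, elevation, kappa) {
  n <- length(azimuth)
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  w <- pmax(-1, pmin(1, w))
  omega <- stats::runif(n, 0, 2 * pi)
  .about_axis(azimuth, elevation, w, omega)
}

#' Simulate listener responses to targets
#'
#' The generative response model, applied per target:
#'
#' 1. With probability `p_fb0 * s` the perceived direction is mirrored
#'    across the plane of the ears (front/rear reversal), the classic
#'    cone-of-confusion error.
#' 2. The magnitude of the lateral angle is inflated by `lateral_bias0 * s`
#'    (at fixed polar angle, clamped to the valid range); the inflated
#'    azimuth is kept.
#' 3. The elevation is set to the target elevation plus
#'    `elevation_bias0 * s_polar` (clamped to `[-90, 90]`), so before noise
#'    the signed elevation error equals the generative bias exactly.
#' 4. The result is perturbed by isotropic von Mises-Fisher noise with
#'    concentration `noise_kappa0 / s`.
#'
#' Here `s` is the listener's adaptation state. For targets spatialized with
#' the untrained HRTF set, only a fraction `polar_transfer` of the
#' elevation-component adaptation applies:
#' `s_polar = 1 - polar_transfer * (1 - s)`; the other components transfer
#' fully. Uses the current R random number stream.
#'
#' @param profile A single cohort row (see [make_cohort()]).
#' @param targets A data frame with columns `azimuth` and `elevation`.
#' @param hrtf `"trained"` or `"untrained"`; scalar or one value per target.
#' @return A tibble with response `azimuth` and `elevation`, one row per
#'   target.
#' @examples
#' cohort <- make_cohort(seed = 1)
#' respond(cohort[1, ], tibble::tibble(azimuth = 0, elevation = 0))
#' @export
respond <- function(profile, targets, hrtf = "trained") {
  stopifnot(all(hrtf %in% c("trained", "untrained")))
  n <- nrow(targets)
  az <- targets$azimuth
  el <- targets$elevation
  s <- adaptation_state(profile)
  s_polar <- ifelse(hrtf == "untrained", 1 - profile$polar_transfer * (1 - s), s)

  # 1. front-back confusion: mirror across the coronal plane (x -> -x)
  confuse <- stats::runif(n) < profile$p_fb0 * s
  az <- ifelse(confuse, (180 - az) %% 360, az)

  # 2. lateral overshoot at fixed polar angle (azimuth carries the overshoot)
  ia <- .to_interaural(az, el)
  lat <- sign(ia$lateral) * pmin(90, abs(ia$lateral) + profile$lateral_bias0 * s)
  d <- .from_interaural(lat, ia$polar)

  # 3. elevation bias (the polar-specific component), anchored on the target
  # elevation so the pre-noise signed elevation error is exactly the bias
  el3 <- pmin(90, pmax(-90, el + profile$elevation_bias0 * s_polar))

  # 4. isotropic angular noise
  out <- .rvmf_about(d$azimuth, el3, profile$noise_kappa0 / s)
  tibble::new_tibble(list(azimuth = out$azimuth, elevation = out$elevation), nrow = n)
}
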