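#' Protocol configuration
#'
#' Collects the tunable parameters of the training/testing protocol: the
#' adaptive target-size staircase, the per-group training-block trial and
#' stimulus-presentation counts, and the testing-block layout.
#'
#' Defaults encode the study protocol this package models: an initial hit
#' window of 25 degrees; target radius shrinking by 10% per level after
#' three consecutive hits and reverting one level after five misses at a
#' level; 12-minute training blocks; testing blocks of 48 targets (12
#' centroids x 4 jittered repeats, three spatialized with the trained HRTF
#' set and one with an untrained set); and a three-day schedule of 9
#' training and 8 testing blocks.
#'
#' Training blocks in the human protocol were time-limited (12 minutes), so
#' per-block trial counts varied; here they are fixed per group. The
#' active-gamified variant loops the stimulus until the listener responds,
#' which slows trials but multiplies presentations, hence the lower trial
#' count and higher `presentations_per_trial`.
#'
#' @param initial_hit_angle Hit window at level 1, degrees.
#' @param shrink_factor Target-radius multiplier per level (0.9 = 10% smaller).
#' @param hits_to_advance Consecutive hits required to advance a level.
#' @param misses_to_revert Misses at a level required to revert one level.
#' @param target_distance Distance to the target object (arbitrary length
#'   unit; cancels in the angular hit criterion).
#' @param trials_per_training_block Named counts per group.
#' @param presentations_per_trial Named stimulus-presentation counts per
#'   training trial (stimulus + feedback replay = 2; the active variant
#'   loops playback).
#' @param test_jitter Testing-target jitter cap, degrees.
#' @param test_repeats Repeats per testing centroid.
#' @param trained_per_centroid Of those repeats, how many use the trained
#'   HRTF set (the remainder use the untrained set).
#' @param block_minutes Duration of one training block, minutes.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(initial_hit_angle = 25,
                            shrink_factor = 0.9,
                            hits_to_advance = 3,
                            misses_to_revert = 5,
                            target_distance = 1,
                            trials_per_training_block = c(
                              control = 0, non_gamified = 60,
                              gamified = 60, active_gamified = 45
                            ),
                            presentations_per_trial = c(
                              non_gamified = 2, gamified = 2,
                              active_gamified = 6
                            ),
                            test_jitter = 20,
                            test_repeats = 4,
                            trained_per_centroid = 3,
                            block_minutes = 12) {
  stopifnot(
    initial_hit_angle > 0, initial_hit_angle < 90,
    shrink_factor > 0, shrink_factor < 1,
    hits_to_advance >= 1, misses_to_revert >= 1,
    trained_per_centroid <= test_repeats
  )
  structure(
    list(
      initial_hit_angle = initial_hit_angle,
      shrink_factor = shrink_factor,
      hits_to_advance = hits_to_advance,
      misses_to_revert = misses_to_revert,
      target_distance = target_distance,
      trials_per_training_block = trials_per_training_block,
      presentations_per_trial = presentations_per_trial,
      test_jitter = test_jitter,
      test_repeats = test_repeats,
      trained_per_centroid = trained_per_centroid,
      block_minutes = block_minutes
    ),
    class = "protocol_config"
  )
}

#' Testing-block target centroids
#'
#' Eight orientations on the horizon at 45-degree azimuth increments from 0,
#' plus four at 45 degrees elevation with azimuths 45, 135, 225 and 315.
#'
#' @return A 12-row tibble with columns `azimuth` and `elevation`.
#' @export
test_centroids <- function() {
  tibble::tibble(
    azimuth = c(seq(0, 315, by = 45), c(45, 135, 225, 315)),
    elevation = c(rep(0, 8), rep(45, 4))
  )
}

#' Angular hit threshold at a staircase level
#'
#' The target is a sphere of radius `r = shrink_factor^(L-1) * d * sin(theta0)`
#' at distance `d`, where `theta0` is the initial hit angle. A response "ray"
#' hits the sphere when its angular deviation is at most
#' `asin(shrink_factor^(L-1) * sin(theta0))`, which this returns in degrees.
#' Thresholds decrease strictly with level.
#'
#' @param level Staircase level (integer >= 1), vectorised.
#' @param cfg A [protocol_config()].
#' @return Hit thresholds in degrees.
#' @examples
#' hit_threshold(1:4, protocol_config())
#' @export
hit_threshold <- function(level, cfg = protocol_config()) {
  stopifnot(all(level >= 1))
  rad2deg(asin(cfg$shrink_factor^(level - 1) * sin(deg2rad(cfg$initial_hit_angle))))
}

#' Initial adaptive staircase state
#'
#' @return A list of class `adaptive_state` with `level = 1` and zeroed
#'   hit/miss counters.
#' @export
adaptive_init <- function() {
  structure(
    list(level = 1L, consecutive_hits = 0L, misses_at_level = 0L),
    class = "adaptive_state"
  )
}

#' Advance the adaptive staircase by one trial
#'
#' After `hits_to_advance` consecutive hits the level increases (the target
#' shrinks by 10%); after `misses_to_revert` misses accumulated at a level
#' (not necessarily consecutive - hits do not clear the miss counter) the
#' level decreases, never below 1. Both counters reset on any level change.
#'
#' @param state An `adaptive_state` (see [adaptive_init()]).
#' @param hit Logical: was the trial a hit?
#' @param cfg A [protocol_config()].
#' @return The updated `adaptive_state`.
#' @examples
#' s <- adaptive_init()
#' s <- adaptive_update(s, TRUE)
#' @export
adaptive_update <- function(state, hit, cfg = protocol_config()) {
  stopifnot(inherits(state, "adaptive_state"), is.logical(hit), length(hit) == 1)
  if (hit) {
    state$consecutive_hits <- state$consecutive_hits + 1L
    if (state$consecutive_hits >= cfg$hits_to_advance) {
      state$level <- state$level + 1L
      state$consecutive_hits <- 0L
      state$misses_at_level <- 0L
    }
  } else {
    state$consecutive_hits <- 0L
    state$misses_at_level <- state$misses_at_level + 1L
    if (state$misses_at_level >= cfg$misses_to_revert) {
      state$level <- max(1L, state$level - 1L)
      state$consecutive_hits <- 0L
      state$misses_at_level <- 0L
    }
  }
  state
}

#' Generate one testing block of targets
#'
#' Produces `12 x test_repeats` targets: each centroid from
#' [test_centroids()] is repeated `test_repeats` times with an independent
#' area-uniform jitter of up to `test_jitter` degrees;
#' `trained_per_centroid` of each centroid's repeats are labelled for the
#' trained HRTF set and the rest for the untrained set. Presentation order
#' is shuffled. Uses the current R random number stream.
#'
#' @param cfg A [protocol_config()].
#' @return A tibble with columns `centroid_az`, `centroid_el`, `hrtf`,
#'   `azimuth`, `elevation`.
#' @export
make_test_block <- function(cfg = protocol_config()) {
  cen <- test_centroids()
  k <- cfg$test_repeats
  grid <- cen[rep(seq_len(nrow(cen)), each = k), ]
  hrtf <- rep(
    c(
      rep("trained", cfg$trained_per_centroid),
      rep("untrained", k - cfg$trained_per_centroid)
    ),
    times = nrow(cen)
  )
  jit <- jitter_within_cap(grid$azimuth, grid$elevation, cfg$test_jitter)
  out <- tibble::tibble(
    centroid_az = grid$azimuth,
    centroid_el = grid$elevation,
    hrtf = hrtf,
    azimuth = jit$azimuth,
    elevation = jit$elevation
  )
  out[sample.int(nrow(out)), ]
}

#' Run one adaptive training block for a virtual listener
#'
#' Draws targets uniformly over the upper hemisphere, obtains responses from
#' the listener profile, scores each trial as a hit when the spherical error
#' is within the current level's [hit_threshold()], and advances the
#' staircase per trial. Responses do not depend on the staircase, so they
#' are drawn vectorised before the sequential staircase pass.
#'
#' @param profile A single listener profile row (see [make_cohort()]).
#' @param state An `adaptive_state` carried across blocks within a day.
#' @param cfg A [protocol_config()].
#' @param n_trials Number of trials; defaults to the group's configured
#'   per-block count.
#' @return A list with `trials` (tibble: target/response angles, `level` in
#'   effect during each trial, `hit`, `presentations`), the final `state`,
#'   and `presentations` (total stimulus presentations in the block).
#' @export
run_training_block <- function(profile, state, cfg = protocol_config(),
                               n_trials = NULL) {
  grp <- as.character(profile$group)
  if (is.null(n_trials)) {
    n_trials <- cfg$trials_per_training_block[[grp]]
  }
  if (n_trials == 0) {
    return(list(
      trials = tibble::tibble(
        target_az = numeric(), target_el = numeric(),
        response_az = numeric(), response_el = numeric(),
        level = integer(), hit = logical(), presentations = integer()
      ),
      state = state, presentations = 0L
    ))
  }
  per_trial <- as.integer(cfg$presentations_per_trial[[grp]])
  targets <- sample_upper_hemisphere(n_trials)
  responses <- respond(profile, targets, hrtf = "trained")
  err <- .angular_distance(
    targets$azimuth, targets$elevation,
    responses$azimuth, responses$elevation
  )
  level <- integer(n_trials)
  hit <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    level[i] <- state$level
    hit[i] <- err[i] <= hit_threshold(state$level, cfg)
    state <- adaptive_update(state, hit[i], cfg)
  }
  list(
    trials = tibble::new_tibble(list(
      target_az = targets$azimuth, target_el = targets$elevation,
      response_az = responses$azimuth, response_el = responses$elevation,
      level = level, hit = hit,
      presentations = rep(per_trial, n_trials)
    ), nrow = n_trials),
    state = state,
    presentations = per_trial * n_trials
  )
}

# Deterministic per-participant-per-block sub-seed (kept well below 2^31).
.sub_seed <- function(seed, participant, block) {
  as.integer((abs(seed) * 7919 + participant * 1009 + block * 7) %% 2147483647L)
}

# day, block type, and completed-training count layout of the study:
# day 1 alternates test/train ([test, train] x 3 + test); days 2 and 3 are
# [test, train x 3, test].
.study_schedule <- function() {
  tibble::tibble(
    day = c(rep(1L, 7), rep(2L, 5), rep(3L, 5)),
    block_type = c(
      c("test", "train", "test", "train", "test", "train", "test"),
      rep(c("test", "train", "train", "train", "test"), 2)
    )
  ) |>
    dplyr::mutate(block_index = dplyr::row_number())
}

#' Simulate the full three-day study for a cohort
#'
#' Runs the complete block schedule for every listener in the cohort: on day
#' one, testing blocks alternate with the three training blocks to capture
#' rapid early learning; on days two and three a testing block opens and
#' closes a session of three training blocks. Control-group listeners sit
#' out the training blocks (no trials, no learning), keeping the testing
#' schedule aligned across groups. Listener adaptation advances by one step
#' per completed training block and only then (no latent learning between
#' days). All randomness derives from `seed` via per-participant-per-block
#' sub-streams, so equal seeds give identical logs.
#'
#' @param cohort A listener cohort (see [make_cohort()]).
#' @param cfg A [protocol_config()].
#' @param seed Integer seed governing every draw in the study.
#' @return A trial-log tibble with one row per trial and columns
#'   `participant_id`, `group`, `day`, `block_index`, `block_type`,
#'   `trial_index`, `hrtf`, `target_az`, `target_el`, `response_az`,
#'   `response_el`, `completed_training_blocks`, `level`, `hit`,
#'   `presentations`. Attributes `seed` and `config_hash` record provenance.
#' @examples
#' cohort <- make_cohort(listener_config(group_sizes = c(
#'   control = 1, non_gamified = 1, gamified = 1, active_gamified = 1
#' )), seed = 7)
#' log <- run_study(cohort, seed = 7)
#' @export
run_study <- function(cohort, cfg = protocol_config(), seed = 1L) {
  schedule <- .study_schedule()
  out <- vector("list", nrow(cohort) * nrow(schedule))
  k <- 0L
  for (p in seq_len(nrow(cohort))) {
    profile <- cohort[p, ]
    is_control <- identical(as.character(profile$group), "control")
    state <- adaptive_init()
    profile$completed_blocks <- 0L
    for (b in seq_len(nrow(schedule))) {
      set.seed(.sub_seed(seed, p, b))
      day <- schedule$day[b]
      type <- schedule$block_type[b]
      if (b > 1 && day != schedule$day[b - 1]) {
        state <- adaptive_init() # staircase restarts each day
      }
      if (type == "test") {
        targets <- make_test_block(cfg)
        responses <- respond(
          profile,
          tibble::tibble(azimuth = targets$azimuth, elevation = targets$elevation),
          hrtf = targets$hrtf
        )
        k <- k + 1L
        nt <- nrow(targets)
        out[[k]] <- tibble::new_tibble(list(
          participant_id = rep(profile$participant_id, nt),
          group = rep(as.character(profile$group), nt),
          day = rep(day, nt), block_index = rep(b, nt),
          block_type = rep("test", nt),
          trial_index = seq_len(nt),
          hrtf = targets$hrtf,
          target_az = targets$azimuth, target_el = targets$elevation,
          response_az = responses$azimuth, response_el = responses$elevation,
          completed_training_blocks = rep(profile$completed_blocks, nt),
          level = rep(NA_integer_, nt), hit = rep(NA, nt),
          presentations = rep(NA_integer_, nt)
        ), nrow = nt)
      } else if (!is_control) {
        blk <- run_training_block(profile, state, cfg)
        state <- blk$state
        if (nrow(blk$trials) > 0) {
          k <- k + 1L
          nt <- nrow(blk$trials)
          out[[k]] <- tibble::new_tibble(list(
            participant_id = rep(profile$participant_id, nt),
            group = rep(as.character(profile$group), nt),
            day = rep(day, nt), block_index = rep(b, nt),
            block_type = rep("train", nt),
            trial_index = seq_len(nt),
            hrtf = rep("trained", nt),
            target_az = blk$trials$target_az, target_el = blk$trials$target_el,
            response_az = blk$trials$response_az,
            response_el = blk$trials$response_el,
            completed_training_blocks = rep(profile$completed_blocks, nt),
            level = blk$trials$level, hit = blk$trials$hit,
            presentations = blk$trials$presentations
          ), nrow = nt)
        }
        profile <- advance_training(profile)
      }
    }
  }
  log <- dplyr::bind_rows(out[seq_len(k)])
  attr(log, "seed") <- seed
  attr(log, "config_hash") <- rlang::hash(unclass(cfg))
  log
}

#' Simulate a complete study from a single seed
#'
#' Convenience wrapper: builds a default cohort and runs [run_study()].
#'
#' @param seed Integer seed for cohort generation and the study.
#' @param cfg A [protocol_config()].
#' @param listener_cfg A [listener_config()].
#' @return A trial-log tibble (see [run_study()]).
#' @export
simulate_study <- function(seed = 1L, cfg = protocol_config(),
                           listener_cfg = listener_config()) {
  cohort <- make_cohort(listener_cfg, seed = .sub_seed(seed, 0L, 0L))
  run_study(cohort, cfg = cfg, seed = seed)
}
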