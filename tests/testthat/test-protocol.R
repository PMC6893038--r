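test_that("hit threshold follows the ray-sphere shrink rule", {
  cfg <- protocol_config()
  expect_equal(hit_threshold(1, cfg), 25)
  expect_equal(
    hit_threshold(2, cfg),
    asin(0.9 * sin(25 * pi / 180)) * 180 / pi,
    tolerance = 1e-9
  )
  thr <- hit_threshold(1:20, cfg)
  expect_true(all(diff(thr) < 0))
  expect_true(all(thr > 0))
})

test_that("staircase advances on three consecutive hits and reverts after five misses", {
  cfg <- protocol_config()
  s <- adaptive_init()
  s$consecutive_hits <- 2L
  s2 <- adaptive_update(s, TRUE, cfg)
  expect_equal(s2$level, 2L)
  expect_equal(s2$consecutive_hits, 0L)
  expect_equal(s2$misses_at_level, 0L)

  s <- adaptive_init()
  s$misses_at_level <- 4L
  s2 <- adaptive_update(s, FALSE, cfg)
  expect_equal(s2$level, 1L) # floor at the initial size
  expect_equal(s2$misses_at_level, 0L)

  s <- adaptive_init()
  s$level <- 3L
  s$misses_at_level <- 4L
  s2 <- adaptive_update(s, FALSE, cfg)
  expect_equal(s2$level, 2L)

  # hits do not clear the accumulated miss count at a level
  s <- adaptive_init()
  s$misses_at_level <- 3L
  s2 <- adaptive_update(s, TRUE, cfg)
  expect_equal(s2$misses_at_level, 3L)
  expect_equal(s2$consecutive_hits, 1L)
})

test_that("staircase level matches the closed form under a perfect responder", {
  cfg <- protocol_config()
  s <- adaptive_init()
  for (n in 1:30) {
    s <- adaptive_update(s, TRUE, cfg)
    expect_equal(s$level, 1 + n %/% 3)
  }
  s <- adaptive_init()
  for (n in 1:50) {
    s <- adaptive_update(s, FALSE, cfg)
    expect_gte(s$level, 1)
  }
  expect_equal(s$level, 1L)
})

test_that("test blocks have the 12x4 layout with a 3:1 HRTF split inside the jitter cap", {
  cfg <- protocol_config()
  cen <- test_centroids()
  expect_true(any(cen$azimuth == 0 & cen$elevation == 0))
  expect_true(any(cen$azimuth == 135 & cen$elevation == 45))
  for (seed in 1:5) {
    set.seed(seed)
    blk <- make_test_block(cfg)
    expect_equal(nrow(blk), 48)
    expect_equal(sum(blk$hrtf == "trained"), 36)
    expect_equal(sum(blk$hrtf == "untrained"), 12)
    split <- blk |>
      dplyr::count(.data$centroid_az, .data$centroid_el, .data$hrtf) |>
      tidyr::pivot_wider(names_from = "hrtf", values_from = "n")
    expect_true(all(split$trained == 3 & split$untrained == 1))
    dev <- angular_distance(blk$centroid_az, blk$centroid_el, blk$azimuth, blk$elevation)
    expect_true(all(dev <= 20 + 1e-9))
  }
})

test_that("training blocks score hits against the current threshold", {
  cfg <- protocol_config()
  set.seed(1)
  veridical <- make_profile()
  res <- run_training_block(veridical, adaptive_init(), cfg, n_trials = 3)
  expect_true(all(res$trials$hit))
  expect_equal(res$state$level, 2L)
  expect_equal(res$trials$level, c(1L, 1L, 1L)) # level in effect during trials
  expect_true(all(res$trials$target_el >= 0)) # upper hemisphere only

  # a wildly biased listener never advances
  set.seed(2)
  bad <- make_profile(elevation_bias0 = -90, lateral_bias0 = 80, p_fb0 = 1)
  res2 <- run_training_block(bad, adaptive_init(), cfg, n_trials = 60)
  expect_equal(res2$state$level, 1L)

  # active variant accrues more presentations at equal trial counts
  set.seed(3)
  act <- make_profile(group = "active_gamified")
  res3 <- run_training_block(act, adaptive_init(), cfg, n_trials = 3)
  expect_gt(res3$presentations, res$presentations)
})

test_that("the three-day schedule yields 8 testing and 9 training blocks", {
  cohort <- make_cohort(small_listener_config(), seed = 4)
  log <- run_study(cohort, seed = 4)
  trained <- dplyr::filter(log, .data$group == "non_gamified", .data$participant_id == log$participant_id[log$group == "non_gamified"][1])
  tests <- dplyr::filter(trained, .data$block_type == "test")
  expect_equal(length(unique(tests$block_index)), 8)
  expect_equal(
    tests |> dplyr::distinct(.data$block_index, .data$completed_training_blocks) |>
      dplyr::arrange(.data$block_index) |> dplyr::pull(.data$completed_training_blocks),
    c(0L, 1L, 2L, 3L, 3L, 6L, 6L, 9L)
  )
  expect_equal(length(unique(trained$block_index[trained$block_type == "train"])), 9)

  ctrl <- dplyr::filter(log, .data$group == "control")
  expect_equal(nrow(dplyr::filter(ctrl, .data$block_type == "train")), 0)
  expect_equal(
    length(unique(ctrl$block_index)), 8
  )
  expect_true(all(ctrl$completed_training_blocks == 0))
  expect_true(all(log$target_el[log$block_type == "train"] >= 0))
})

test_that("equal seeds give identical trial logs", {
  cohort <- make_cohort(small_listener_config(), seed = 9)
  log1 <- run_study(cohort, seed = 11)
  log2 <- run_study(cohort, seed = 11)
  expect_identical(log1, log2)
  log3 <- run_study(cohort, seed = 12)
  expect_false(identical(log1$response_az, log3$response_az))
})
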