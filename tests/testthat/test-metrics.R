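test_that("spherical and lateral errors follow their definitions", {
  log <- make_toy_log(
    target_az = c(10, 0, 45, 30, 30),
    target_el = c(20, 0, 0, 0, 0),
    response_az = c(10, 180, 45, 30, 350),
    response_el = c(20, 0, 30, 0, 0)
  )
  m <- trial_metrics(log)
  expect_equal(m$spherical_error, c(0, 180, 30, 0, 40), tolerance = 1e-9)
  # target lateral 30, response lateral -10 -> |(-10) - 30| = 40
  expect_equal(m$lateral_error[5], 40, tolerance = 1e-9)
  expect_true(all(m$lateral_error <= 180))
})

test_that("front-back gates, confusion flags and signed measures are correct", {
  log <- make_toy_log(
    target_az = c(80, 10, 10, 170, 20, 45),
    target_el = c(0, 0, 0, 0, 0, 45),
    response_az = c(80, 170, 20, 10, 320, 45),
    response_el = c(0, 0, 0, 0, 0, 30)
  )
  m <- trial_metrics(log)
  # |lateral| of an 80-deg-azimuth horizon target is ~80 > 65: ineligible
  expect_false(m$fb_eligible[1])
  expect_true(is.na(m$fb_confused[1]))
  expect_true(is.na(m$signed_fb[1]))
  # front target, rear response: eligible + confused, signed_fb = -1
  expect_true(m$fb_eligible[2] && m$fb_confused[2])
  expect_equal(m$signed_fb[2], -1)
  expect_true(is.na(m$pae[2])) # confused trials carry no PAE
  expect_true(is.na(m$signed_lateral[2])) # wrong hemisphere: no signed biases
  expect_true(is.na(m$signed_elevation[2]))
  # front target, front response: not confused
  expect_false(m$fb_confused[3])
  expect_equal(m$signed_fb[3], 0)
  # rear target, front response: signed_fb = +1
  expect_equal(m$signed_fb[4], 1)
  # target lateral 20, response lateral -40, same hemisphere: +20
  expect_equal(m$signed_lateral[5], 20, tolerance = 1e-9)
  # pure elevation change: signed elevation -15
  expect_equal(m$signed_elevation[6], -15, tolerance = 1e-9)
})

test_that("polar angle error wraps and scales by the target lateral cosine", {
  t1 <- from_interaural(60, 0)
  r1 <- from_interaural(60, 20)
  t2 <- from_interaural(0, 170)
  r2 <- from_interaural(0, -170)
  log <- make_toy_log(
    target_az = c(t1$azimuth, t2$azimuth, 10),
    target_el = c(t1$elevation, t2$elevation, 0),
    response_az = c(r1$azimuth, r2$azimuth, 10),
    response_el = c(r1$elevation, r2$elevation, 0)
  )
  m <- trial_metrics(log)
  expect_equal(m$pae[1], 20 * cos(pi / 3), tolerance = 1e-9) # 10
  expect_equal(m$pae[2], 20, tolerance = 1e-9) # wrap(340) = 20
  expect_equal(m$pae[3], 0)
})

test_that("on-axis (degenerate) trials are excluded from PAE and signed elevation only", {
  log <- make_toy_log(
    target_az = c(90, 10),
    target_el = c(0, 0),
    response_az = c(80, 90),
    response_el = c(0, 0)
  )
  m <- trial_metrics(log)
  expect_true(all(is.na(m$pae)))
  expect_true(all(is.na(m$signed_elevation)))
  expect_false(any(is.na(m$spherical_error)))
  expect_false(any(is.na(m$lateral_error)))
})

test_that("block aggregation reproduces hand-computed summaries", {
  # 3 trials with spherical errors 10, 20, 180 -> median 20
  log <- make_toy_log(
    target_az = c(0, 0, 0),
    target_el = c(0, 0, 0),
    response_az = c(10, 20, 180),
    response_el = c(0, 0, 0)
  )
  s <- summarise_blocks(log)
  expect_equal(s$median_spherical, 20, tolerance = 1e-9)

  # 12 eligible trials, 5 confused -> 41.67%
  log2 <- make_toy_log(
    target_az = rep(10, 12),
    target_el = rep(0, 12),
    response_az = c(rep(170, 5), rep(15, 7)),
    response_el = rep(0, 12)
  )
  s2 <- summarise_blocks(log2)
  expect_equal(s2$n_fb_eligible, 12)
  expect_equal(s2$fb_rate, 100 * 5 / 12, tolerance = 1e-9)

  # veridical listener: every summary at zero
  set.seed(5)
  d <- sample_upper_hemisphere(40)
  log3 <- make_toy_log(d$azimuth, d$elevation, d$azimuth, d$elevation)
  s3 <- summarise_blocks(log3)
  expect_equal(s3$median_spherical, 0)
  expect_equal(s3$median_lateral, 0)
  expect_equal(s3$fb_rate, 0)
  expect_equal(s3$mean_signed_lateral, 0)
  expect_equal(s3$mean_signed_elevation, 0)
  expect_equal(s3$mean_signed_fb, 0)
})

test_that("fb rate is flagged absent when no trial is eligible", {
  log <- make_toy_log(
    target_az = c(90, 270), target_el = c(0, 0),
    response_az = c(90, 270), response_el = c(0, 0)
  )
  s <- summarise_blocks(log)
  expect_false(s$fb_rate_defined)
  expect_true(is.na(s$fb_rate))
})

test_that("metric invariants hold on random trials", {
  set.seed(21)
  tgt <- random_directions(2000)
  rsp <- random_directions(2000)
  log <- make_toy_log(tgt$azimuth, tgt$elevation, rsp$azimuth, rsp$elevation)
  m <- trial_metrics(log)
  lat_t <- to_interaural(tgt$azimuth, tgt$elevation)$lateral
  ok <- !is.na(m$pae)
  expect_true(all(m$pae[ok] <= 180 * cos(lat_t[ok] * pi / 180) + 1e-9))
  # zero spherical error <=> zero lateral error and zero pae
  zero <- m$spherical_error < 1e-9
  expect_true(all(m$lateral_error[zero] < 1e-9))
  expect_true(all(m$pae[zero & ok] < 1e-9))
  # mirroring responses about the median plane leaves unsigned metrics alone
  log_m <- log
  log_m$target_az <- (360 - log_m$target_az) %% 360
  log_m$response_az <- (360 - log_m$response_az) %% 360
  mm <- trial_metrics(log_m)
  expect_equal(mm$spherical_error, m$spherical_error, tolerance = 1e-9)
  expect_equal(mm$lateral_error, m$lateral_error, tolerance = 1e-9)
  expect_equal(mm$pae, m$pae, tolerance = 1e-9)
  expect_equal(mm$fb_confused, m$fb_confused)
})

test_that("fb-eligible fraction of hemisphere-uniform targets matches the cap fraction", {
  set.seed(31)
  d <- sample_upper_hemisphere(1e5)
  log <- make_toy_log(d$azimuth, d$elevation, d$azimuth, d$elevation)
  m <- trial_metrics(log)
  expect_equal(mean(m$fb_eligible), sin(65 * pi / 180), tolerance = 0.01)
})

test_that("sector summary bins azimuth into eight 45-degree sectors", {
  log <- make_toy_log(
    target_az = rep(180, 4), target_el = rep(0, 4),
    response_az = rep(90, 4), response_el = rep(0, 4)
  )
  s <- sector_summary(log)
  expect_equal(nrow(s), 8)
  expect_equal(s$mean_spherical[s$sector_center == 180], 90, tolerance = 1e-9)
  expect_true(all(is.na(s$mean_spherical[s$sector_center != 180])))
  # boundary azimuth 22.5 belongs to the 45-deg sector (half-open bins)
  log2 <- make_toy_log(22.5, 0, 22.5, 0)
  s2 <- sector_summary(log2)
  expect_equal(s2$n_trials[s2$sector_center == 45], 1)
  expect_equal(s2$n_trials[s2$sector_center == 0], 0)
  # wrap-around: azimuth 350 belongs to the 0-deg sector
  s3 <- sector_summary(make_toy_log(350, 0, 350, 0))
  expect_equal(s3$n_trials[s3$sector_center == 0], 1)
  # veridical: all present sector means zero
  set.seed(2)
  d <- sample_upper_hemisphere(400)
  s4 <- sector_summary(make_toy_log(d$azimuth, d$elevation, d$azimuth, d$elevation))
  expect_true(all(s4$mean_spherical < 1e-6, na.rm = TRUE))
})
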