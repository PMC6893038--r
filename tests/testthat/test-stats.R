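test_that("paired change test matches the closed-form oracle and flags degeneracy", {
  before <- c(30, 40, 50, 60)
  after <- c(25, 38, 41, 52)
  res <- paired_change_test(before, after)
  d <- after - before
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 3L)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)

  same <- paired_change_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- paired_change_test(c(10, 12, 14), c(8, 10, 12))
  expect_true(const$degenerate)
  expect_equal(const$mean_diff, -2)
  expect_true(is.na(const$t))

  set.seed(13)
  for (i in 1:20) {
    b <- rnorm(8, 40, 10)
    a <- b - rnorm(8, 5, 3)
    mine <- paired_change_test(b, a)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ANCOVA coefficients match the normal-equations oracle", {
  set.seed(14)
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = 4),
    initial = c(35, 42, 38, 45, 40, 36, 44, 39),
    final = c(30, 33, 31, 36, 25, 22, 28, 24)
  )
  res <- ancova_group_effect(d, final, initial, group)
  X <- cbind(1, d$initial, as.numeric(d$group == "b"))
  beta <- solve(t(X) %*% X, t(X) %*% d$final)
  expect_equal(unname(coef(res$model)), as.numeric(beta), tolerance = 1e-9)
  # adjusted means at the grand-mean covariate
  adj_a <- beta[1] + beta[2] * mean(d$initial)
  adj_b <- adj_a + beta[3]
  expect_equal(
    sort(res$adjusted_means$adjusted_mean), sort(c(adj_a, adj_b)),
    tolerance = 1e-9
  )
})

test_that("ANCOVA recovers a known group offset and is invariant to covariate centring", {
  set.seed(15)
  n <- 40
  delta <- 6
  d <- tibble::tibble(
    group = rep(c("a", "b"), each = n),
    initial = rnorm(2 * n, 40, 5)
  )
  d$final <- 5 + 0.8 * d$initial - delta * (d$group == "b") + rnorm(2 * n, 0, 1)
  res <- ancova_group_effect(d, final, initial, group)
  diff_hat <- diff(res$adjusted_means$adjusted_mean[order(res$adjusted_means$group)])
  expect_equal(as.numeric(diff_hat), -delta, tolerance = 1)
  expect_lt(res$p, 0.001)

  d2 <- dplyr::mutate(d, initial = initial - 100)
  res2 <- ancova_group_effect(d2, final, initial, group)
  expect_equal(res2$adjusted_means$adjusted_mean, res$adjusted_means$adjusted_mean,
    tolerance = 1e-9
  )
  expect_equal(res2$statistic, res$statistic, tolerance = 1e-9)
  # tukey table covers all pairwise contrasts
  expect_equal(nrow(res$pairwise), 1)
  expect_s3_class(glance(res), "tbl_df")

  expect_error(
    ancova_group_effect(dplyr::filter(d, group == "a"), final, initial, group),
    "two groups"
  )
})

test_that("exposure-improvement correlation hits the deterministic limits", {
  mk_log <- function(improvement, presentations) {
    n <- length(improvement)
    ids <- sprintf("P%02d", seq_len(n))
    purrr::map_dfr(seq_len(n), function(i) {
      dplyr::bind_rows(
        # initial test block: error = improvement + 5, via an elevation offset
        make_toy_log(
          target_az = c(0, 0), target_el = c(10, 10),
          response_az = c(0, 0), response_el = c(10, 10) + improvement[i] + 5,
          participant_id = ids[i], block_index = 1L, block_type = "test"
        ),
        # training block carrying the presentation total
        make_toy_log(
          target_az = 0, target_el = 10, response_az = 0, response_el = 10,
          participant_id = ids[i], block_index = 2L, block_type = "train"
        ) |> dplyr::mutate(presentations = presentations[i]),
        # final test block: constant error of 5
        make_toy_log(
          target_az = c(0, 0), target_el = c(10, 10),
          response_az = c(0, 0), response_el = c(15, 15),
          participant_id = ids[i], block_index = 3L, block_type = "test"
        )
      )
    })
  }
  pres <- c(100, 140, 180, 220, 260)
  log <- mk_log(improvement = 0.1 * pres, presentations = pres)
  res <- presentations_vs_improvement(log)
  expect_equal(res$r, 1, tolerance = 1e-9)

  log2 <- mk_log(improvement = rep(8, 5), presentations = pres)
  res2 <- presentations_vs_improvement(log2)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$r))
})

test_that("identical per-condition changes produce null trained-vs-untrained contrasts", {
  d <- tidyr::expand_grid(
    participant_id = sprintf("P%02d", 1:6),
    hrtf = c("trained", "untrained"),
    block_index = c(1L, 2L)
  ) |>
    dplyr::mutate(
      group = "gamified",
      pid = as.integer(factor(participant_id)),
      wobble = c(0.5, -0.3, 0.8, -0.6, 0.2, -0.4)[pid],
      median_spherical = ifelse(block_index == 1, 40 + 2 * pid, 30 + 2 * pid + wobble),
      median_lateral = median_spherical / 2,
      median_pae = median_spherical / 3,
      fb_rate = ifelse(block_index == 1, 40 + pid, 25 + pid + wobble)
    )
  res <- trained_vs_untrained(d)
  expect_equal(nrow(res), 4)
  expect_true(all(res$degenerate))
  expect_equal(res$mean_delta_trained, res$mean_delta_untrained)
  expect_true(all(res$ancova_p > 0.99))
})

test_that("partial polar transfer shows up as a trained-condition PAE advantage", {
  deltas <- sapply(1:4, function(s) {
    log <- simulate_study(
      seed = s,
      listener_cfg = small_listener_config(polar_transfer = 0)
    )
    sums <- summarise_blocks(
      dplyr::filter(log, .data$block_type == "test"),
      by_hrtf = TRUE
    )
    res <- trained_vs_untrained(sums)
    r <- res[res$metric == "pae", ]
    r$mean_delta_trained - r$mean_delta_untrained
  })
  expect_lt(mean(deltas), 0) # trained condition improves more on average
})
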