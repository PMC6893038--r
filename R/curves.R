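#' Fit an exponential learning curve
#'
#' Fits `y = a * exp(-b * x) + c` by bounded least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}) with `a >= 0` and `b >= 0`.
#' `x` is the number of completed training blocks and `y` the localization
#' error, so `a + c` is the fitted initial error, `c` the asymptote and `b`
#' the learning rate per block. To avoid the flat-data local trap the fit is
#' multi-started from `c0 = min(y)`, `a0 = max(y) - min(y)` and
#' `b0 in {0.1, 0.3, 1.0}`; the lowest residual sum of squares wins, ties
#' going to the smallest `b`.
#'
#' The adjusted R-squared uses `p = 3` parameters:
#' `1 - (1 - R^2) (n - 1) / (n - 4)`; it can be negative for data an
#' exponential describes poorly (e.g. flat, noisy series) and is `NA` when
#' `n = 4` leaves no residual degrees of freedom. Exactly constant `y`
#' (zero total sum of squares) is reported with `R^2 = 0`, so its adjusted
#' value is negative.
#'
#' @param x Non-negative numeric predictor (completed training blocks).
#' @param y Response (error, degrees). At least 4 points.
#' @return An object of class `exp_fit`: a list with elements `a`, `b`, `c`,
#'   `r2`, `adj_r2`, `rss`, `n_points`, `converged` and the fitting `data`.
#'   Supports [generics::tidy()], [generics::glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @examples
#' x <- 0:9
#' fit <- fit_exponential(x, 20 * exp(-0.5 * x) + 25)
#' tidy(fit)
#' @export
fit_exponential <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 4) stop("at least 4 points are required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  c0 <- min(y)
  a0 <- max(y) - min(y)
  take_if_better <- function(best, cand) {
    if (is.null(cand)) return(best)
    if (is.null(best) ||
      cand$rss < best$rss * (1 - 1e-10) ||
      (abs(cand$rss - best$rss) <= 1e-10 * max(1, best$rss) && cand$b < best$b)) {
      cand
    } else {
      best
    }
  }
  lm_try <- function(start) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a * exp(-b * x) + c,
        data = dat,
        start = start,
        lower = c(a = 0, b = 0, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    list(
      a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
      rss = sum(stats::residuals(fit)^2)
    )
  }
  best <- NULL
  for (b0 in c(0.1, 0.3, 1.0)) {
    best <- take_if_better(best, lm_try(list(a = a0, b = b0, c = c0)))
  }
  # Profiled grid over b with (a, c) solved linearly: immune to the singular
  # gradients that flat or degenerate-x data produce in the LM starts.
  for (bg in c(0, exp(seq(log(0.02), log(4), length.out = 40)))) {
    e <- exp(-bg * x)
    cand <- if (bg == 0 || stats::sd(e) < 1e-12) {
      list(a = 0, b = bg, c = mean(y), rss = sum((y - mean(y))^2))
    } else {
      cf <- stats::coef(stats::lm(y ~ e))
      a_hat <- unname(cf[2])
      if (!is.finite(a_hat) || a_hat < 0) {
        list(a = 0, b = bg, c = mean(y), rss = sum((y - mean(y))^2))
      } else {
        fitted <- cf[1] + a_hat * e
        list(a = a_hat, b = bg, c = unname(cf[1]), rss = sum((y - fitted)^2))
      }
    }
    best <- take_if_better(best, cand)
  }
  # polish the winner
  best <- take_if_better(
    best,
    lm_try(list(a = max(best$a, 1e-8), b = max(best$b, 1e-8), c = best$c))
  )
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < 1e-12) 0 else 1 - best$rss / tss
  adj_r2 <- if (n > 4) 1 - (1 - r2) * (n - 1) / (n - 4) else NA_real_
  out <- list(
    a = best$a, b = best$b, c = best$c, r2 = r2, adj_r2 = adj_r2,
    rss = best$rss, n_points = n, converged = TRUE,
    data = tibble::tibble(x = x, y = y)
  )
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Exponential learning-curve fit: y = a exp(-b x) + c\n")
  cat(sprintf(
    "  a = %.4g, b = %.4g, c = %.4g  (n = %d, adj R^2 = %.3f)\n",
    x$a, x$b, x$c, x$n_points,
    if (is.na(x$adj_r2)) NA_real_ else x$adj_r2
  ))
  invisible(x)
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  object$a * exp(-object$b * x) + object$c
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(x$a, x$b, x$c)
  )
}

#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    r2 = x$r2, adj_r2 = x$adj_r2, rss = x$rss,
    n_points = x$n_points, converged = x$converged
  )
}

#' Fit per-group learning curves from block summaries
#'
#' For each group, averages the per-participant block medians of `value`
#' over participants at each completed-training-block count (keeping
#' repeated counts - e.g. the closing and opening testing blocks of
#' consecutive days - as separate points) and fits [fit_exponential()] to
#' the group means.
#'
#' The time axis is schedule-matched: each testing block's x is the number
#' of training blocks a trained participant has completed at that point in
#' the schedule (the maximum `completed_training_blocks` across groups at
#' that `block_index`). Control participants complete no training, but sit
#' the same testing schedule; this puts their (flat) series on the same
#' axis as the trained groups rather than collapsing it onto x = 0.
#'
#' @param block_summaries Output of [summarise_blocks()] on testing-block
#'   trials.
#' @param value Column to fit (unquoted); default `median_spherical`.
#' @return A tibble with one row per group: `a`, `b`, `c`, `adj_r2`,
#'   `n_points`, `converged` and a list column `fit` of `exp_fit` objects.
#' @export
fit_group_curves <- function(block_summaries, value = median_spherical) {
  axis <- block_summaries |>
    dplyr::group_by(.data$block_index) |>
    dplyr::summarise(
      completed_training_blocks = max(.data$completed_training_blocks),
      .groups = "drop"
    )
  means <- block_summaries |>
    dplyr::select(-"completed_training_blocks") |>
    dplyr::left_join(axis, by = "block_index") |>
    dplyr::group_by(.data$group, .data$block_index, .data$completed_training_blocks) |>
    dplyr::summarise(y = mean({{ value }}, na.rm = TRUE), .groups = "drop")
  means |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      fit = list(fit_exponential(.data$completed_training_blocks, .data$y)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      a = purrr::map_dbl(.data$fit, "a"),
      b = purrr::map_dbl(.data$fit, "b"),
      c = purrr::map_dbl(.data$fit, "c"),
      adj_r2 = purrr::map_dbl(.data$fit, "adj_r2"),
      n_points = purrr::map_int(.data$fit, "n_points"),
      converged = purrr::map_lgl(.data$fit, "converged")
    ) |>
    dplyr::relocate("fit", .after = dplyr::last_col())
}

#' Derived timescale summary of learning-curve fits
#'
#' Averages fit parameters across groups: the mean initial error is
#' `mean(a) + mean(c)`, the mean final (asymptotic) error `mean(c)`, and
#' the learning half-life `ln(2) / mean(b)` in training blocks, also
#' expressed in minutes of training via the block duration.
#'
#' @param fits A data frame with columns `a`, `b`, `c` (e.g. from
#'   [fit_group_curves()], typically restricted to the trained groups), or
#'   a single `exp_fit`.
#' @param block_minutes Minutes of training per block (default 12).
#' @return A one-row tibble: `initial_error`, `final_error`,
#'   `half_life_blocks` (infinite when `mean(b) = 0`), `half_life_minutes`,
#'   `n_fits`.
#' @examples
#' fits <- tibble::tibble(
#'   a = c(17.3, 15.7, 20.7), b = c(0.270, 0.320, 0.710),
#'   c = c(23.6, 32.5, 20.4)
#' )
#' derived_summary(fits)
#' @export
derived_summary <- function(fits, block_minutes = 12) {
  if (inherits(fits, "exp_fit")) {
    fits <- tibble::tibble(a = fits$a, b = fits$b, c = fits$c)
  }
  stopifnot(all(c("a", "b", "c") %in% names(fits)), nrow(fits) >= 1)
  mb <- mean(fits$b)
  hl <- if (mb == 0) Inf else log(2) / mb
  tibble::tibble(
    initial_error = mean(fits$a) + mean(fits$c),
    final_error = mean(fits$c),
    half_life_blocks = hl,
    half_life_minutes = hl * block_minutes,
    n_fits = nrow(fits)
  )
}

#' Overnight consolidation deltas
#'
#' For each participant, the change in median spherical error from the last
#' testing block of day 1 to the first of day 2, and from the last of day 2
#' to the first of day 3. Values near zero indicate consolidation (gains
#' retained overnight) without latent learning (no improvement during
#' rest). Participants missing any of the four required testing blocks are
#' dropped with a warning.
#'
#' @param block_summaries Output of [summarise_blocks()] on testing-block
#'   trials.
#' @return A tibble with one row per participant: `delta_day1_to_2` and
#'   `delta_day2_to_3` (degrees; positive = error increased overnight).
#' @export
consolidation_deltas <- function(block_summaries) {
  need <- c("participant_id", "day", "block_index", "median_spherical")
  missing <- setdiff(need, names(block_summaries))
  if (length(missing) > 0) {
    stop("block_summaries is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  edges <- block_summaries |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(
      first = .data$median_spherical[which.min(.data$block_index)],
      last = .data$median_spherical[which.max(.data$block_index)],
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "day", values_from = c("first", "last"),
      names_sep = "_day"
    )
  need_cols <- c("last_day1", "first_day2", "last_day2", "first_day3")
  missing_cols <- setdiff(need_cols, names(edges))
  if (length(missing_cols) > 0) {
    stop("log lacks testing blocks on some days: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  complete <- stats::complete.cases(edges[, need_cols])
  if (any(!complete)) {
    warning(sum(!complete), " participant(s) missing required testing blocks; excluded")
    edges <- edges[complete, ]
  }
  keys <- block_summaries |>
    dplyr::distinct(.data$participant_id, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("participant_id", "group")))
  edges |>
    dplyr::transmute(
      .data$participant_id,
      delta_day1_to_2 = .data$first_day2 - .data$last_day1,
      delta_day2_to_3 = .data$first_day3 - .data$last_day2
    ) |>
    dplyr::left_join(keys, by = "participant_id") |>
    dplyr::relocate(dplyr::any_of("group"), .after = "participant_id")
}
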