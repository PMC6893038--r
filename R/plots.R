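#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted exponential learning curve
#'
#' @param object An `exp_fit` from [fit_exponential()].
#' @param ... Unused.
#' @return A ggplot: the fitted points and the fitted exponential.
#' @exportS3Method ggplot2::autoplot
autoplot.exp_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = 200)
  )
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(
      x = "Completed training blocks",
      y = "Error (deg)",
      title = sprintf(
        "y = %.3g exp(-%.3g x) + %.3g", object$a, object$b, object$c
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot group learning curves with exponential fits
#'
#' Group means of per-participant median errors against completed training
#' blocks, with the fitted exponentials overlaid.
#'
#' @param block_summaries Output of [summarise_blocks()] on testing blocks.
#' @param fits Optional output of [fit_group_curves()]; computed if absent.
#' @param value Column to plot (unquoted); default `median_spherical`.
#' @return A ggplot.
#' @export
plot_learning_curves <- function(block_summaries, fits = NULL,
                                 value = median_spherical) {
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
    dplyr::summarise(
      y = mean({{ value }}, na.rm = TRUE),
      se = stats::sd({{ value }}, na.rm = TRUE) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  if (is.null(fits)) fits <- fit_group_curves(block_summaries, {{ value }})
  curves <- fits |>
    dplyr::filter(.data$converged) |>
    dplyr::mutate(
      curve = purrr::map(.data$fit, function(f) {
        x <- seq(min(f$data$x), max(f$data$x), length.out = 200)
        tibble::tibble(completed_training_blocks = x, y = predict(f, tibble::tibble(x = x)))
      })
    ) |>
    dplyr::select("group", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(means, ggplot2::aes(
    x = .data$completed_training_blocks, y = .data$y, colour = .data$group
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$se, ymax = .data$y + .data$se),
      width = 0.15, alpha = 0.6
    ) +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(
      x = "Completed training blocks",
      y = "Group mean of participant median error (deg)",
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' Polar plot of mean spherical error by azimuth sector
#'
#' @param sectors Output of [sector_summary()], optionally with an extra
#'   grouping column `phase` (e.g. before/after) to colour by.
#' @return A ggplot in polar coordinates.
#' @export
plot_error_by_sector <- function(sectors) {
  aes <- if ("phase" %in% names(sectors)) {
    ggplot2::aes(
      x = .data$sector_center, y = .data$mean_spherical,
      fill = .data$phase
    )
  } else {
    ggplot2::aes(x = .data$sector_center, y = .data$mean_spherical)
  }
  ggplot2::ggplot(sectors, aes) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 40) +
    ggplot2::coord_polar(start = -pi / 9, direction = -1) +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, 45), limits = c(-22.5, 337.5)) +
    ggplot2::labs(x = "Target azimuth (deg)", y = "Mean spherical error (deg)") +
    ggplot2::theme_minimal()
}

#' Plot signed response biases before and after training
#'
#' Per-group means of the signed lateral, signed elevation and signed
#' front-back measures in the first and last testing blocks.
#'
#' @param block_summaries Output of [summarise_blocks()] on testing blocks.
#' @return A ggplot, faceted by measure.
#' @export
plot_signed_biases <- function(block_summaries) {
  edges <- block_summaries |>
    dplyr::group_by(.data$group, .data$participant_id) |>
    dplyr::arrange(.data$block_index, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(
        c("mean_signed_lateral", "mean_signed_elevation", "mean_signed_fb"),
        list(before = dplyr::first, after = dplyr::last)
      ),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(-c("group", "participant_id"),
      names_to = c("measure", "phase"),
      names_pattern = "mean_signed_(.*)_(before|after)"
    )
  edges$phase <- factor(edges$phase, levels = c("before", "after"))
  ggplot2::ggplot(edges, ggplot2::aes(
    x = .data$group, y = .data$value, fill = .data$phase
  )) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Signed bias", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
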