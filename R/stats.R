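#' Paired t-test on per-participant before/after values
#'
#' Two-sided paired t-test on `after - before`, computed from the closed
#' form `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Zero-variance differences are flagged `degenerate`: when every
#' difference is exactly zero the test is reported as `t = 0, p = 1`;
#' otherwise `t` and `p` are `NA`.
#'
#' @param before,after Paired numeric vectors, length >= 3.
#' @return A one-row tibble: `mean_diff`, `t`, `df`, `p`, `n`, `degenerate`.
#' @examples
#' paired_change_test(c(30, 40, 50, 60), c(25, 38, 41, 52))
#' @export
paired_change_test <- function(before, after) {
  if (length(before) != length(after)) {
    stop("before and after must be paired (equal length)", call. = FALSE)
  }
  ok <- stats::complete.cases(before, after)
  d <- (after - before)[ok]
  n <- length(d)
  if (n < 3) stop("at least 3 complete pairs are required", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < 1e-12) {
    return(tibble::tibble(
      mean_diff = m,
      t = if (abs(m) < 1e-12) 0 else NA_real_,
      df = n - 1L,
      p = if (abs(m) < 1e-12) 1 else NA_real_,
      n = n, degenerate = TRUE
    ))
  }
  t <- m / (s / sqrt(n))
  tibble::tibble(
    mean_diff = m, t = t, df = n - 1L,
    p = 2 * stats::pt(-abs(t), n - 1),
    n = n, degenerate = FALSE
  )
}

#' One-way ANCOVA on final scores with an initial-score covariate
#'
#' Fits `final ~ initial + group` (homogeneous slopes) and tests the group
#' factor with the covariate already in the model, the standard one-way
#' ANCOVA controlling for initial performance. Covariate-adjusted group
#' means are evaluated at the grand-mean initial score, and all pairwise
#' group contrasts are compared with Tukey's HSD family-wise adjustment
#' (both via \pkg{emmeans}). A slope-heterogeneity diagnostic (the
#' `initial:group` interaction p-value) is reported but does not alter the
#' model.
#'
#' @param data A data frame with one row per participant.
#' @param final,initial,group Unquoted column names for the response,
#'   covariate and grouping factor.
#' @return An object of class `ancova_fit` with the underlying `lm`, the
#'   group F-test (`statistic`, `df`, `df_resid`, `p`), `adjusted_means`
#'   (tibble), `pairwise` (tibble with Tukey-adjusted p-values) and
#'   `slope_heterogeneity_p`. Supports [generics::tidy()] (the pairwise
#'   contrasts) and [generics::glance()] (the omnibus test).
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   group = rep(c("a", "b"), each = 8),
#'   initial = rnorm(16, 40, 5),
#'   final = initial - ifelse(group == "b", 10, 2) + rnorm(16)
#' )
#' ancova_group_effect(d, final, initial, group)
#' @export
ancova_group_effect <- function(data, final, initial, group) {
  df <- tibble::tibble(
    final = dplyr::pull(data, {{ final }}),
    initial = dplyr::pull(data, {{ initial }}),
    group = factor(dplyr::pull(data, {{ group }}))
  )
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2) {
    stop("at least two groups are required", call. = FALSE)
  }
  if (any(table(df$group) < 2)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  fit <- stats::lm(final ~ initial + group, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: group effects are not estimable", call. = FALSE)
  }
  an <- stats::anova(fit) # sequential; group entered after the covariate
  grp_row <- an["group", ]
  emm <- emmeans::emmeans(fit, "group")
  adj <- tibble::as_tibble(as.data.frame(emm))
  names(adj)[names(adj) == "emmean"] <- "adjusted_mean"
  pw <- tibble::as_tibble(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  ))
  het <- stats::anova(stats::lm(final ~ initial * group, data = df))
  het_p <- het["initial:group", "Pr(>F)"]
  out <- list(
    model = fit,
    statistic = grp_row[["F value"]],
    df = grp_row[["Df"]],
    df_resid = an["Residuals", "Df"],
    p = grp_row[["Pr(>F)"]],
    adjusted_means = adj,
    pairwise = pw,
    slope_heterogeneity_p = het_p
  )
  class(out) <- "ancova_fit"
  out
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf(
    "One-way ANCOVA (final ~ initial + group): F(%d, %d) = %.3f, p = %.4g\n",
    x$df, x$df_resid, x$statistic, x$p
  ))
  cat("Adjusted means:\n")
  print(x$adjusted_means)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ancova_fit <- function(x, ...) {
  out <- x$pairwise
  names(out)[names(out) == "contrast"] <- "contrast"
  out
}

#' @exportS3Method generics::glance
glance.ancova_fit <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, df_resid = x$df_resid, p = x$p,
    slope_heterogeneity_p = x$slope_heterogeneity_p
  )
}

#' Correlate training exposure with improvement
#'
#' Pearson correlation between each trained participant's total number of
#' stimulus presentations during training and their improvement in median
#' spherical error (initial minus final testing block). A dissociation
#' (small `r`) indicates that time on task, rather than raw stimulus
#' exposure, drives differences between training variants.
#'
#' @param log A trial log from [run_study()] (or any log with training
#'   `presentations` and testing-block metrics columns).
#' @return A one-row tibble: `r`, `df`, `p`, `n`, `degenerate` (`TRUE` with
#'   `NA` statistics when either variable is constant).
#' @export
presentations_vs_improvement <- function(log) {
  trained <- dplyr::filter(log, .data$group != "control")
  pres <- trained |>
    dplyr::filter(.data$block_type == "train") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(presentations = sum(.data$presentations), .groups = "drop")
  tests <- summarise_blocks(dplyr::filter(trained, .data$block_type == "test"))
  improvement <- tests |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      improvement = .data$median_spherical[which.min(.data$block_index)] -
        .data$median_spherical[which.max(.data$block_index)],
      .groups = "drop"
    )
  d <- dplyr::inner_join(pres, improvement, by = "participant_id")
  if (nrow(d) < 3) stop("at least 3 trained participants are required", call. = FALSE)
  if (stats::sd(d$presentations) < 1e-12 || stats::sd(d$improvement) < 1e-12) {
    return(tibble::tibble(
      r = NA_real_, df = nrow(d) - 2L, p = NA_real_,
      n = nrow(d), degenerate = TRUE
    ))
  }
  ct <- stats::cor.test(d$presentations, d$improvement, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
    n = nrow(d), degenerate = FALSE
  )
}

#' Trained- versus untrained-HRTF condition contrasts
#'
#' Quantifies how far training gains transfer to the untrained HRTF set.
#' For each error measure (median spherical, median lateral, median PAE and
#' the front-back confusion rate), computes each trained participant's
#' initial-to-final change separately for the trained and untrained
#' conditions, then (i) a paired t-test on the per-participant difference in
#' changes pooled across training groups and (ii) a one-way ANCOVA of final
#' scores with HRTF condition as the fixed factor and initial score as the
#' covariate.
#'
#' @param block_summaries Output of
#'   `summarise_blocks(trials, by_hrtf = TRUE)` on testing-block trials.
#' @param exclude_control Drop control participants before pooling
#'   (default `TRUE`, matching the pooled-trained-groups analysis).
#' @return A tibble with one row per metric: mean changes per condition,
#'   the paired test (`t`, `df`, `p`) and the ANCOVA condition effect
#'   (`ancova_F`, `ancova_df`, `ancova_df_resid`, `ancova_p`).
#' @export
trained_vs_untrained <- function(block_summaries, exclude_control = TRUE) {
  if (!"hrtf" %in% names(block_summaries)) {
    stop("block_summaries must be computed with by_hrtf = TRUE", call. = FALSE)
  }
  d <- block_summaries
  if (exclude_control && "group" %in% names(d)) {
    d <- dplyr::filter(d, .data$group != "control")
  }
  metrics <- c(
    spherical = "median_spherical", lateral = "median_lateral",
    pae = "median_pae", fb_rate = "fb_rate"
  )
  ends <- d |>
    dplyr::group_by(.data$participant_id, .data$hrtf) |>
    dplyr::arrange(.data$block_index, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(unname(metrics)),
        list(initial = dplyr::first, final = dplyr::last)
      ),
      .groups = "drop"
    )
  complete <- ends |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull(.data$participant_id)
  dropped <- setdiff(unique(ends$participant_id), complete)
  if (length(dropped) > 0) {
    warning(
      length(dropped),
      " participant(s) lack one HRTF condition; excluded: ",
      paste(dropped, collapse = ", ")
    )
    ends <- dplyr::filter(ends, .data$participant_id %in% complete)
  }
  purrr::map_dfr(names(metrics), function(mname) {
    col <- metrics[[mname]]
    wide <- ends |>
      dplyr::select(
        "participant_id", "hrtf",
        initial = dplyr::all_of(paste0(col, "_initial")),
        final = dplyr::all_of(paste0(col, "_final"))
      ) |>
      dplyr::mutate(delta = .data$final - .data$initial)
    tr <- dplyr::filter(wide, .data$hrtf == "trained")
    un <- dplyr::filter(wide, .data$hrtf == "untrained")
    keep <- intersect(tr$participant_id, un$participant_id)
    tr <- tr[match(keep, tr$participant_id), ]
    un <- un[match(keep, un$participant_id), ]
    pt <- paired_change_test(un$delta, tr$delta)
    anc <- ancova_group_effect(wide, final, initial, hrtf)
    tibble::tibble(
      metric = mname,
      n = length(keep),
      mean_delta_trained = mean(tr$delta, na.rm = TRUE),
      mean_delta_untrained = mean(un$delta, na.rm = TRUE),
      t = pt$t, df = pt$df, p = pt$p, degenerate = pt$degenerate,
      ancova_F = anc$statistic, ancova_df = anc$df,
      ancova_df_resid = anc$df_resid, ancova_p = anc$p
    )
  })
}
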