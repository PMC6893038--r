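#' Per-trial localization-error metrics
#'
#' Computes, for every trial in a log, the four standard localization-error
#' measures and their signed bias variants:
#'
#' * `spherical_error` — great-circle angle between target and response.
#' * `lateral_error` — absolute difference of interaural lateral angles.
#' * `pae` — polar angle error: the absolute polar-angle difference, wrapped
#'   to the shortest arc on the cone of confusion (`[0, 180]`), scaled by the
#'   cosine of the target lateral angle. Absent (`NA`) for front-back
#'   confused trials, trials ineligible for the front-back measure, and
#'   trials whose target or response lies on the interaural axis.
#' * `fb_eligible` / `fb_confused` — a trial enters the front-back confusion
#'   measure only when the target's absolute lateral angle is at most 65
#'   degrees (more than 25 degrees away from the interaural axis); among
#'   eligible trials, `fb_confused` flags responses in the wrong front/rear
#'   hemisphere.
#' * `signed_lateral` — `|lateral(response)| - |lateral(target)|`; positive
#'   values mean responses more lateral than the target. Only computed when
#'   the response lies in the target's front/rear hemisphere.
#' * `signed_elevation` — `elevation(response) - elevation(target)`; positive
#'   values mean responses above the target. Same hemisphere gate; also
#'   absent for on-axis (degenerate) targets or responses.
#' * `signed_fb` — for eligible trials: +1 for a rear target perceived in
#'   front, -1 for a front target perceived behind, 0 otherwise.
#'
#' @param trials A data frame with columns `target_az`, `target_el`,
#'   `response_az`, `response_el` (degrees). Other columns are preserved.
#' @param fb_lateral_limit Eligibility gate for the front-back measures:
#'   maximum absolute *target* lateral angle, in degrees. Default 65.
#' @return The input as a tibble with the metric columns appended.
#' @examples
#' log <- tibble::tibble(
#'   target_az = c(10, 10), target_el = c(0, 0),
#'   response_az = c(20, 170), response_el = c(5, 0)
#' )
#' trial_metrics(log)
#' @export
trial_metrics <- function(trials, fb_lateral_limit = 65) {
  required <- c("target_az", "target_el", "response_az", "response_el")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop("trials is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tgt <- .to_interaural(trials$target_az, trials$target_el)
  rsp <- .to_interaural(trials$response_az, trials$response_el)
  tgt_front <- .dir_to_vec(trials$target_az, trials$target_el)$x >= 0
  rsp_front <- .dir_to_vec(trials$response_az, trials$response_el)$x >= 0
  same_hemi <- tgt_front == rsp_front
  degenerate <- tgt$degenerate | rsp$degenerate

  fb_eligible <- abs(tgt$lateral) <= fb_lateral_limit
  fb_confused <- ifelse(fb_eligible, !same_hemi, NA)

  dpol <- abs(rsp$polar - tgt$polar)
  dpol <- pmin(dpol, 360 - dpol) # shortest arc around the cone of confusion
  pae <- dpol * cos(deg2rad(tgt$lateral))
  pae[!fb_eligible | !same_hemi | degenerate] <- NA_real_

  signed_lateral <- abs(rsp$lateral) - abs(tgt$lateral)
  signed_lateral[!same_hemi] <- NA_real_
  signed_elevation <- trials$response_el - trials$target_el
  signed_elevation[!same_hemi | degenerate] <- NA_real_

  signed_fb <- dplyr::case_when(
    !fb_eligible ~ NA_real_,
    !tgt_front & rsp_front ~ 1,
    tgt_front & !rsp_front ~ -1,
    TRUE ~ 0
  )

  out <- tibble::as_tibble(trials)
  out$spherical_error <- .angular_distance(
    trials$target_az, trials$target_el,
    trials$response_az, trials$response_el
  )
  out$lateral_error <- abs(rsp$lateral - tgt$lateral)
  out$fb_eligible <- fb_eligible
  out$fb_confused <- fb_confused
  out$pae <- pae
  out$signed_lateral <- signed_lateral
  out$signed_elevation <- signed_elevation
  out$signed_fb <- signed_fb
  out
}

#' Per-participant block summaries
#'
#' Aggregates per-trial metrics to one row per participant and testing (or
#' training) block: the medians of the spherical, lateral and polar angle
#' errors, the front-back confusion rate as a percentage of eligible trials,
#' and the means of the signed bias measures. Medians of an even number of
#' values are the midpoint of the two central values (`stats::median`).
#'
#' @param trials A trial log (see [trial_metrics()]); metric columns are
#'   computed on the fly if absent.
#' @param by_hrtf If `TRUE`, summarise separately per HRTF condition (the
#'   `hrtf` column), e.g. to contrast trained vs untrained conditions.
#' @return A tibble with one row per participant x block (x condition), with
#'   columns `median_spherical`, `median_lateral`, `median_pae`, `fb_rate`
#'   (percent; `NA` with `fb_rate_defined = FALSE` when no trial was
#'   eligible), `mean_signed_lateral`, `mean_signed_elevation`,
#'   `mean_signed_fb`, and counts `n_trials`, `n_fb_eligible`,
#'   `n_fb_confused`.
#' @export
summarise_blocks <- function(trials, by_hrtf = FALSE) {
  if (!"spherical_error" %in% names(trials)) {
    trials <- trial_metrics(trials)
  }
  keys <- intersect(
    c(
      "participant_id", "group", "day", "block_index", "block_type",
      "completed_training_blocks"
    ),
    names(trials)
  )
  if (by_hrtf) {
    if (!"hrtf" %in% names(trials)) {
      stop("by_hrtf = TRUE requires an 'hrtf' column", call. = FALSE)
    }
    keys <- c(keys, "hrtf")
  }
  if (!"participant_id" %in% keys || !"block_index" %in% keys) {
    stop("trials must carry 'participant_id' and 'block_index' columns", call. = FALSE)
  }
  med <- function(x) stats::median(x, na.rm = TRUE)
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      median_spherical = med(.data$spherical_error),
      median_lateral = med(.data$lateral_error),
      median_pae = ifelse(all(is.na(.data$pae)), NA_real_, med(.data$pae)),
      n_fb_eligible = sum(.data$fb_eligible),
      n_fb_confused = sum(.data$fb_confused, na.rm = TRUE),
      fb_rate_defined = .data$n_fb_eligible > 0,
      fb_rate = ifelse(.data$n_fb_eligible > 0,
        100 * .data$n_fb_confused / .data$n_fb_eligible, NA_real_
      ),
      mean_signed_lateral = mean(.data$signed_lateral, na.rm = TRUE),
      mean_signed_elevation = mean(.data$signed_elevation, na.rm = TRUE),
      mean_signed_fb = mean(.data$signed_fb, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Mean spherical error by azimuth sector
#'
#' Bins trials by target azimuth into eight 45-degree sectors centred on
#' 0, 45, ..., 315 degrees (half-open bins `[centre - 22.5, centre + 22.5)`)
#' and reports the mean spherical angle error in each. Sectors with no
#' trials get `NA`.
#'
#' @inheritParams summarise_blocks
#' @return A tibble with columns `sector_center`, `n_trials` and
#'   `mean_spherical`, always eight rows.
#' @export
sector_summary <- function(trials) {
  if (nrow(trials) == 0) stop("trials must be nonempty", call. = FALSE)
  if (!"spherical_error" %in% names(trials)) {
    trials <- trial_metrics(trials)
  }
  centers <- seq(0, 315, by = 45)
  sector <- (floor((trials$target_az + 22.5) / 45) %% 8) * 45
  tibble::tibble(sector_center = sector, spherical_error = trials$spherical_error) |>
    dplyr::group_by(.data$sector_center) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_spherical = mean(.data$spherical_error),
      .groups = "drop"
    ) |>
    tidyr::complete(
      sector_center = centers,
      fill = list(n_trials = 0L, mean_spherical = NA_real_)
    ) |>
    dplyr::arrange(.data$sector_center)
}
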