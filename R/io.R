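.log_required_cols <- c(
  "participant_id", "group", "day", "block_index", "block_type",
  "trial_index", "hrtf", "target_az", "target_el", "response_az",
  "response_el", "completed_training_blocks", "level", "hit"
)

.known_groups <- c("control", "non_gamified", "gamified", "active_gamified")

#' Write a trial log to CSV
#'
#' Angles are serialized in degrees at full double precision (readr writes
#' the shortest representation that round-trips), so
#' `read_trial_log(write_trial_log(x))` reproduces every field exactly.
#' Provenance attributes (`seed`, `config_hash`) are stored as `#`-prefixed
#' header comments.
#'
#' @param log A trial-log tibble (see [run_study()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  .validate_log(log)
  header <- character()
  if (!is.null(attr(log, "seed"))) {
    header <- c(header, paste0("# seed: ", attr(log, "seed")))
  }
  if (!is.null(attr(log, "config_hash"))) {
    header <- c(header, paste0("# config_hash: ", attr(log, "config_hash")))
  }
  # serialize doubles at 17 significant digits so values round-trip exactly
  out <- dplyr::mutate(
    tibble::as_tibble(log),
    dplyr::across(dplyr::where(is.double), ~ sprintf("%.17g", .x))
  )
  csv <- readr::format_csv(out)
  writeLines(c(header, sub("\n$", "", csv)), path)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads a CSV written by [write_trial_log()] (or produced externally with
#' the same schema) and validates it: all required columns present, angles
#' within range, group labels known, keys unique. Unknown extra columns are
#' preserved. Validation failures are reported with row numbers.
#'
#' @param path CSV file path.
#' @return A trial-log tibble; `seed` and `config_hash` header comments, if
#'   present, are restored as attributes.
#' @export
read_trial_log <- function(path) {
  head_lines <- readLines(path, n = 20)
  meta <- grep("^# ", head_lines, value = TRUE)
  # base read.csv: correctly-rounded double parsing, so angles written at 17
  # significant digits come back bit-identical
  classes <- c(
    participant_id = "character", group = "character", day = "integer",
    block_index = "integer", block_type = "character",
    trial_index = "integer", hrtf = "character",
    target_az = "numeric", target_el = "numeric",
    response_az = "numeric", response_el = "numeric",
    completed_training_blocks = "integer", level = "integer",
    hit = "logical"
  )
  header <- utils::read.csv(path, comment.char = "#", nrows = 1, check.names = FALSE)
  log <- tibble::as_tibble(utils::read.csv(
    path,
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = classes[intersect(names(classes), names(header))]
  ))
  .validate_log(log)
  seed_line <- grep("^# seed: ", meta, value = TRUE)
  if (length(seed_line) == 1) {
    attr(log, "seed") <- as.integer(sub("^# seed: ", "", seed_line))
  }
  hash_line <- grep("^# config_hash: ", meta, value = TRUE)
  if (length(hash_line) == 1) {
    attr(log, "config_hash") <- sub("^# config_hash: ", "", hash_line)
  }
  log
}

.validate_log <- function(log) {
  missing <- setdiff(.log_required_cols, names(log))
  if (length(missing) > 0) {
    stop("trial log is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop(sprintf(
        "trial log: %s (rows %s%s)", what,
        paste(utils::head(idx, 5), collapse = ", "),
        if (length(idx) > 5) ", ..." else ""
      ), call. = FALSE)
    }
  }
  bad_row(
    !is.finite(log$target_az) | log$target_az < 0 | log$target_az >= 360,
    "target_az out of [0, 360)"
  )
  bad_row(
    !is.finite(log$response_az) | log$response_az < 0 | log$response_az >= 360,
    "response_az out of [0, 360)"
  )
  bad_row(
    !is.finite(log$target_el) | abs(log$target_el) > 90,
    "target_el out of [-90, 90]"
  )
  bad_row(
    !is.finite(log$response_el) | abs(log$response_el) > 90,
    "response_el out of [-90, 90]"
  )
  bad_row(!(log$group %in% .known_groups), "unknown group label")
  bad_row(!(log$block_type %in% c("test", "train")), "unknown block_type")
  bad_row(
    !(log$completed_training_blocks %in% 0:9),
    "completed_training_blocks out of 0..9"
  )
  keys <- paste(log$participant_id, log$block_index, log$trial_index)
  bad_row(duplicated(keys), "duplicate (participant, block_index, trial_index)")
  invisible(TRUE)
}

#' Default study configuration
#'
#' The full protocol + listener configuration as a plain nested list,
#' suitable for writing to YAML and editing.
#'
#' @return A named list with components `protocol` and `listener` mirroring
#'   the arguments of [protocol_config()] and [listener_config()], plus a
#'   `config_version` marker.
#' @export
default_study_config <- function() {
  list(
    config_version = 1L,
    protocol = unclass(protocol_config()) |> lapply(function(x) {
      if (!is.null(names(x))) as.list(x) else x
    }),
    listener = unclass(listener_config()) |> lapply(function(x) {
      if (!is.null(names(x)) && !is.list(x)) as.list(x) else x
    })
  )
}

#' Read a study configuration from YAML
#'
#' Missing keys fall back to defaults; unknown keys are an error (fail
#' loud rather than silently ignoring a typo).
#'
#' @param path YAML file path. `NULL` returns the defaults.
#' @return A list with `protocol` (a [protocol_config()]) and `listener`
#'   (a [listener_config()]), plus the raw list and its hash.
#' @export
read_study_config <- function(path = NULL) {
  defaults <- default_study_config()
  raw <- if (is.null(path)) defaults else yaml::read_yaml(path)
  check_keys <- function(x, ref, where) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown) > 0) {
      stop(sprintf(
        "unknown config key(s) in %s: %s", where,
        paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
  }
  check_keys(raw, defaults, "top level")
  merged <- defaults
  for (section in c("protocol", "listener")) {
    if (!is.null(raw[[section]])) {
      check_keys(raw[[section]], defaults[[section]], section)
      merged[[section]] <- utils::modifyList(defaults[[section]], raw[[section]])
    }
  }
  to_named <- function(x) {
    if (is.list(x) && length(x) > 0 && all(vapply(x, is.numeric, TRUE))) {
      unlist(x)
    } else {
      x
    }
  }
  pc <- lapply(merged$protocol, to_named)
  lc <- merged$listener
  lc_named <- lapply(lc[setdiff(names(lc), "jitter_sd")], to_named)
  list(
    protocol = do.call(protocol_config, pc),
    listener = do.call(listener_config, c(lc_named, list(jitter_sd = lc$jitter_sd))),
    raw = merged,
    hash = rlang::hash(merged)
  )
}

#' Assemble a plain-text study report
#'
#' Runs the full analysis chain on a trial log and formats a Markdown
#' report: provenance (seed, config hash), group sizes, initial and final
#' error summaries per group, mean spherical error by azimuth sector before
#' and after training, per-group learning-curve fits with the derived
#' timescale summary, consolidation deltas, and the trained- vs
#' untrained-HRTF contrasts. Deterministic for a given log.
#'
#' @param log A trial log (see [run_study()] / [read_trial_log()]).
#' @param block_minutes Minutes per training block, for the half-life
#'   conversion.
#' @return A character vector of report lines, invisibly printable with
#'   `writeLines()`.
#' @export
build_report <- function(log, block_minutes = 12) {
  tests <- dplyr::filter(log, .data$block_type == "test")
  sums <- summarise_blocks(tests)
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c(
    "# Sound-localization study report",
    "",
    paste0("- trials: ", nrow(log)),
    paste0("- participants: ", length(unique(log$participant_id))),
    paste0("- seed: ", attr(log, "seed") %||% "unknown"),
    paste0("- config hash: ", attr(log, "config_hash") %||% "unknown"),
    ""
  )
  sizes <- log |>
    dplyr::distinct(.data$participant_id, .data$group) |>
    dplyr::count(.data$group)
  lines <- c(
    lines, "## Group sizes", "",
    paste0("- ", sizes$group, ": ", sizes$n), ""
  )

  edges <- sums |>
    dplyr::group_by(.data$group, .data$participant_id) |>
    dplyr::arrange(.data$block_index, .by_group = TRUE) |>
    dplyr::summarise(
      initial = dplyr::first(.data$median_spherical),
      final = dplyr::last(.data$median_spherical),
      initial_fb = dplyr::first(.data$fb_rate),
      final_fb = dplyr::last(.data$fb_rate),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::everything() & !dplyr::any_of("participant_id"), mean),
      .groups = "drop"
    )
  lines <- c(
    lines,
    "## Mean of per-participant median spherical error (deg) and F-B rate (%)",
    "",
    "| group | initial | final | initial F-B | final F-B |",
    "|---|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %s | %s |",
      edges$group, fmt(edges$initial), fmt(edges$final),
      fmt(edges$initial_fb, 1), fmt(edges$final_fb, 1)
    ),
    ""
  )

  first_block <- min(tests$block_index)
  last_block <- max(tests$block_index)
  sec_pre <- sector_summary(dplyr::filter(tests, .data$block_index == first_block))
  sec_post <- sector_summary(dplyr::filter(tests, .data$block_index == last_block))
  lines <- c(
    lines, "## Mean spherical error by target azimuth sector (deg)", "",
    "| sector | before | after |", "|---|---|---|",
    sprintf(
      "| %d | %s | %s |", sec_pre$sector_center,
      fmt(sec_pre$mean_spherical), fmt(sec_post$mean_spherical)
    ),
    ""
  )

  fits <- fit_group_curves(sums)
  lines <- c(
    lines, "## Exponential learning-curve fits (a exp(-b x) + c)", "",
    "| group | a | b | c | adj R2 |", "|---|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %s | %s |",
      fits$group, fmt(fits$a), fmt(fits$b, 3), fmt(fits$c), fmt(fits$adj_r2, 3)
    ),
    ""
  )
  trained_fits <- dplyr::filter(fits, .data$group != "control")
  if (nrow(trained_fits) > 0) {
    ds <- derived_summary(trained_fits, block_minutes = block_minutes)
    lines <- c(
      lines,
      sprintf(
        paste0(
          "Derived summary (trained groups): initial error %s deg, final error ",
          "%s deg, half-life %s blocks (~%s min)."
        ),
        fmt(ds$initial_error, 1), fmt(ds$final_error, 1),
        fmt(ds$half_life_blocks), fmt(ds$half_life_minutes, 1)
      ),
      ""
    )
  }

  cons <- consolidation_deltas(sums) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      d12 = mean(.data$delta_day1_to_2), d23 = mean(.data$delta_day2_to_3),
      .groups = "drop"
    )
  lines <- c(
    lines, "## Overnight change in median spherical error (deg)", "",
    "| group | day 1 to 2 | day 2 to 3 |", "|---|---|---|",
    sprintf("| %s | %s | %s |", cons$group, fmt(cons$d12), fmt(cons$d23)),
    ""
  )

  tvu <- trained_vs_untrained(summarise_blocks(tests, by_hrtf = TRUE))
  lines <- c(
    lines, "## Trained vs untrained HRTF (pooled trained groups)", "",
    "| metric | delta trained | delta untrained | t | p | ANCOVA p |",
    "|---|---|---|---|---|---|",
    sprintf(
      "| %s | %s | %s | %s | %s | %s |",
      tvu$metric, fmt(tvu$mean_delta_trained), fmt(tvu$mean_delta_untrained),
      fmt(tvu$t), fmt(tvu$p, 4), fmt(tvu$ancova_p, 4)
    ),
    ""
  )
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
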