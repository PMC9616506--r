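#' Tumor volume from caliper measurements
#'
#' Ellipsoid approximation `V = pi * l * s^2 / 6` (mm^3) from the long (`l`)
#' and short (`s`) caliper sides in mm. If `l < s` the operands are swapped
#' with a warning, since `l` is defined as the long side.
#'
#' @param l Long side, mm (vectorised).
#' @param s Short side, mm.
#' @return Volumes in mm^3.
#' @examples
#' volume_from_caliper(10, 10) # 523.6 mm^3
#' @export
volume_from_caliper <- function(l, s) {
  check_numeric(l, "l"); check_numeric(s, "s")
  if (any(l < 0) || any(s < 0)) abort("Caliper sides must be non-negative.")
  swap <- l < s
  if (any(swap)) {
    warn("Swapping l/s where l < s (l is defined as the long side).")
    tmp <- l
    l <- ifelse(swap, s, l)
    s <- ifelse(swap, tmp, s)
  }
  pi * l * s^2 / 6
}

#' Default preclinical response thresholds
#'
#' Threshold set used by [classify_response()], following the Pediatric
#' Preclinical Testing Program conventions: progressive disease at >= 25%
#' volume increase, partial response at >= 50% regression, complete response
#' below a measurable minimum of 100 mm^3, and relapse when a tumor regrows
#' above 200 mm^3 after a complete response or after surgical resection.
#' All values are plain config keys and are echoed into classification
#' output.
#'
#' @return A named list: `pd_threshold` (1.25), `pr_threshold` (0.5),
#'   `measurable_min` (100), `relapse_min` (200).
#' @export
response_thresholds <- function() {
  list(
    pd_threshold = 1.25,
    pr_threshold = 0.5,
    measurable_min = 100,
    relapse_min = 200
  )
}

#' Classify per-mouse treatment response from a volume series
#'
#' Relative volume `r(t) = V(t) / V(baseline)` is tracked against the
#' treatment window; the baseline is the first observation at or after
#' `baseline_day` (randomization). Default classes:
#' complete response (CR) when the minimum volume drops below the measurable
#' minimum; maintained CR (MCR) when the final in-window observation is still
#' below it; partial response (PR) when `min r <= 0.5` without CR;
#' progressive disease (PD) when `max r >= 1.25` with `min r > 0.5`;
#' stable disease (SD) otherwise. Relapse is flagged when the volume rises
#' above `relapse_min` after a complete response or after the surgery day.
#'
#' @param series Data frame with columns `day` and `volume` (mm^3), days
#'   strictly increasing; or columns `day`, `l`, `s` (caliper mm), converted
#'   via [volume_from_caliper()].
#' @param baseline_day Randomization day (default: first observed day).
#' @param window Length-2 numeric, treatment window in days (default
#'   `c(baseline_day, max(day))`).
#' @param surgery_day Optional surgical-resection day.
#' @param thresholds Threshold list, see [response_thresholds()].
#' @return An object of class `response_call`: one-row tibble with
#'   `response` (PD/SD/PR/CR/MCR), `relapse`, `min_volume`,
#'   `min_relative`, `max_relative`, `baseline_volume` plus the thresholds
#'   used (as attribute `thresholds`).
#' @export
classify_response <- function(series, baseline_day = NULL, window = NULL,
                              surgery_day = NA_real_,
                              thresholds = response_thresholds()) {
  series <- as_tibble(series)
  if (!"volume" %in% names(series)) {
    check_columns(series, c("day", "l", "s"), "series")
    series$volume <- volume_from_caliper(series$l, series$s)
  }
  check_columns(series, c("day", "volume"), "series")
  series <- arrange(series, .data$day)
  if (nrow(series) < 2) abort("At least two observations are required.")
  if (any(diff(series$day) <= 0)) abort("Days must be strictly increasing.")
  if (any(series$volume < 0)) abort("Volumes must be non-negative.")

  baseline_day <- baseline_day %||% min(series$day)
  base_idx <- which(series$day >= baseline_day)[1]
  if (is.na(base_idx)) abort("No observation at or after the baseline day.")
  v0 <- series$volume[base_idx]
  if (v0 <= 0) abort("Baseline volume must be positive.")
  window <- window %||% c(baseline_day, max(series$day))

  obs <- series[series$day >= baseline_day, ]
  in_window <- obs[obs$day <= window[2], ]
  r <- obs$volume / v0
  min_r <- min(r); max_r <- max(r)
  min_v <- min(obs$volume)

  th <- thresholds
  cr <- min_v < th$measurable_min
  response <- if (cr) {
    final_in_window <- in_window$volume[nrow(in_window)]
    if (final_in_window < th$measurable_min) "MCR" else "CR"
  } else if (min_r <= th$pr_threshold) {
    "PR"
  } else if (max_r >= th$pd_threshold) {
    "PD"
  } else {
    "SD"
  }

  # relapse: regrowth beyond relapse_min after the first sub-measurable
  # observation or after surgical resection
  relapse <- FALSE
  cr_day <- if (cr) obs$day[which(obs$volume < th$measurable_min)[1]] else NA
  anchor <- suppressWarnings(min(c(cr_day, surgery_day), na.rm = TRUE))
  if (is.finite(anchor)) {
    after <- obs[obs$day > anchor, ]
    relapse <- any(after$volume > th$relapse_min)
  }

  out <- tibble(
    response = factor(response, levels = c("PD", "SD", "PR", "CR", "MCR")),
    relapse = relapse,
    baseline_volume = v0,
    min_volume = min_v,
    min_relative = min_r,
    max_relative = max_r,
    day_min = obs$day[which.min(obs$volume)],
    day_max = obs$day[which.max(obs$volume)]
  )
  attr(out, "thresholds") <- th
  class(out) <- c("response_call", class(out))
  out
}

#' Classify every mouse in a volume table
#'
#' @param volumes Data frame with columns `mouse_id`, `group`, `day`,
#'   `volume` (or `l`/`s`), optionally `surgery_day` (constant per mouse).
#' @inheritParams classify_response
#' @return A tibble, one row per mouse, with `mouse_id`, `group` and the
#'   [classify_response()] columns.
#' @export
classify_cohort <- function(volumes, baseline_day = NULL, window = NULL,
                            thresholds = response_thresholds()) {
  check_columns(volumes, c("mouse_id", "group", "day"), "volumes")
  as_tibble(volumes) |>
    group_by(.data$mouse_id, .data$group) |>
    dplyr::group_modify(function(df, key) {
      sday <- if ("surgery_day" %in% names(df)) df$surgery_day[1] else NA_real_
      classify_response(df, baseline_day, window, sday, thresholds)
    }) |>
    ungroup()
}

#' Tally response outcomes per treatment group
#'
#' Counts and integer-rounded percentages of each response class and of
#' relapse within a group of classified mice.
#'
#' @param calls Data frame of response calls (e.g. from [classify_cohort()])
#'   with columns `response` and `relapse`, optionally `group`.
#' @param group Optional group label to filter on.
#' @return A tibble with one row per response class plus a `relapse` row:
#'   `outcome`, `n`, `total`, `percent`.
#' @examples
#' calls <- tibble::tibble(
#'   response = factor(rep("CR", 9), levels = c("PD", "SD", "PR", "CR", "MCR")),
#'   relapse = c(TRUE, TRUE, rep(FALSE, 7))
#' )
#' tally_outcomes(calls) # 2 of 9 relapsed: 22%
#' @export
tally_outcomes <- function(calls, group = NULL) {
  check_columns(calls, c("response", "relapse"), "calls")
  if (!is.null(group)) {
    check_columns(calls, "group", "calls")
    calls <- calls[calls$group == group, ]
  }
  n_total <- nrow(calls)
  if (n_total == 0) abort("No calls in the requested group.")
  classes <- c("PD", "SD", "PR", "CR", "MCR")
  counts <- c(
    as.integer(table(factor(calls$response, levels = classes))),
    sum(calls$relapse)
  )
  tibble(
    outcome = c(classes, "relapse"),
    n = counts,
    total = n_total,
    percent = round(100 * counts / n_total)
  )
}
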