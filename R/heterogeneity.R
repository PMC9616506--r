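check_frequencies <- function(f, tol = 1e-6, what = "frequencies") {
  check_numeric(f, what)
  if (length(f) == 0) abort(sprintf("`%s` must be non-empty.", what))
  if (any(f < -tol | f > 1 + tol)) {
    abort(sprintf("`%s` must lie in [0, 1].", what))
  }
  if (abs(sum(f) - 1) > tol) {
    abort(sprintf(
      "`%s` must sum to 1 (got %.6f).", what, sum(f)
    ))
  }
  invisible(f)
}

#' Copy-number aberration burden (CNAB) of a tumor
#'
#' CNAB summarises the non-stem copy-number load of a tumor as the
#' frequency-weighted sum of absolute copy-number deviations:
#' `CNAB = sum over clones of f(clone) * sum over that clone's non-stem
#' events of |copy deviation from diploid|`. Events present in the stem
#' (shared by all tumors of the model) are excluded, so the burden compares
#' treatment groups on the aberrations acquired within the model.
#'
#' @param clone_freqs Data frame with columns `clone` and `frequency`
#'   (frequencies must sum to 1).
#' @param clone_events Data frame with columns `clone`, `event` and
#'   `copy_deviation` (signed deviation from the diploid state; the absolute
#'   value enters the burden). Clones without rows carry no events.
#' @param stem_events Character vector of stem event identifiers to exclude
#'   (default none).
#' @return A single non-negative number.
#' @examples
#' freqs <- tibble::tibble(clone = c("a", "b"), frequency = c(0.6, 0.4))
#' evs <- tibble::tibble(
#'   clone = c("a", "b", "b"), event = c("g1", "g1", "l1"),
#'   copy_deviation = c(1, 1, -1)
#' )
#' cnab(freqs, evs) # 0.6 * 1 + 0.4 * 2 = 1.4
#' @export
cnab <- function(clone_freqs, clone_events, stem_events = character(0)) {
  check_columns(clone_freqs, c("clone", "frequency"), "clone_freqs")
  check_columns(clone_events, c("clone", "event", "copy_deviation"),
                "clone_events")
  check_frequencies(clone_freqs$frequency)
  burden_per_clone <- clone_events |>
    filter(!.data$event %in% stem_events) |>
    group_by(.data$clone) |>
    summarise(burden = sum(abs(.data$copy_deviation)), .groups = "drop")
  joined <- clone_freqs |>
    left_join(burden_per_clone, by = "clone") |>
    mutate(burden = dplyr::coalesce(.data$burden, 0))
  sum(joined$frequency * joined$burden)
}

#' Simpson's index of diversity over clone frequencies
#'
#' `Ds = 1 - sum(f^2)`: 0 for a monoclonal tumor, approaching `1 - 1/k` for k
#' equally frequent clones.
#'
#' @param frequencies Numeric clone frequencies summing to 1 (within 1e-6).
#' @return The diversity index in \[0, 1).
#' @examples
#' simpson_diversity(c(1))        # 0, no clonal variation
#' simpson_diversity(c(0.5, 0.5)) # 0.5
#' @export
simpson_diversity <- function(frequencies) {
  check_frequencies(frequencies)
  1 - sum(frequencies^2)
}

# convergence-style event matching (same chrom + direction, reciprocal
# overlap >= 50%) used for event-level private-aberration counting
events_match <- function(a, b, min_reciprocal_overlap = 0.5) {
  if (a$chrom != b$chrom || a$direction != b$direction) return(FALSE)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  ov > 0 &&
    ov >= min_reciprocal_overlap * (a$end - a$start) &&
    ov >= min_reciprocal_overlap * (b$end - b$start)
}

#' Fraction of private aberrations per tumor
#'
#' Inter-tumor heterogeneity within a model: for each tumor, the fraction of
#' its non-stem units observed in no other tumor of the set. Units are clones
#' by default (matched by exact event-set equality); event-level matching
#' (same chromosome and direction, reciprocal overlap of at least 50%) is
#' available for sensitivity analysis.
#'
#' @param tumors For `unit = "clones"`: a named list, one element per tumor,
#'   each a list of clone event sets (character vectors). For
#'   `unit = "events"`: a named list of event tibbles with columns `chrom`,
#'   `start`, `end`, `direction`.
#' @param unit `"clones"` or `"events"`.
#' @param stem_events Stem events excluded before clone-set comparison /
#'   event counting (character vector of event ids for clones mode; ignored
#'   in events mode, where the caller should pre-filter).
#' @return A tibble with columns `tumor_id`, `n_units`, `n_private`,
#'   `private_fraction`.
#' @export
private_aberration_fraction <- function(tumors, unit = c("clones", "events"),
                                        stem_events = character(0)) {
  unit <- match.arg(unit)
  if (length(tumors) < 2 || is.null(names(tumors))) {
    abort("At least two named tumors are required for inter-tumor comparison.")
  }
  nms <- names(tumors)
  if (unit == "clones") {
    sets <- purrr::map(tumors, function(clones) {
      purrr::map(clones, function(s) sort(setdiff(s, stem_events)))
    })
    rows <- purrr::map_dfr(nms, function(t1) {
      mine <- sets[[t1]]
      mine <- mine[lengths(mine) > 0]
      others <- unlist(
        purrr::map(setdiff(nms, t1), function(t2) sets[[t2]]),
        recursive = FALSE
      )
      private <- purrr::map_lgl(mine, function(s) {
        !any(purrr::map_lgl(others, function(o) identical(s, o)))
      })
      tibble(
        tumor_id = t1, n_units = length(mine),
        n_private = sum(private),
        private_fraction = if (length(mine) == 0) 0 else mean(private)
      )
    })
  } else {
    rows <- purrr::map_dfr(nms, function(t1) {
      mine <- as_tibble(tumors[[t1]])
      others <- bind_rows(tumors[setdiff(nms, t1)])
      private <- purrr::map_lgl(seq_len(nrow(mine)), function(i) {
        a <- mine[i, ]
        !any(purrr::map_lgl(
          seq_len(nrow(others)),
          function(j) events_match(a, others[j, ])
        ))
      })
      tibble(
        tumor_id = t1, n_units = nrow(mine), n_private = sum(private),
        private_fraction = if (nrow(mine) == 0) 0 else mean(private)
      )
    })
  }
  rows
}

#' Nesting-validated fish-plot data for one tumor over time
#'
#' Prepares clone-frequency trajectories for fish-plot rendering: validates
#' that at every observed time point each parent clone's frequency is at
#' least the sum of its children's (within `tol`), fills clones absent at a
#' time point with frequency 0, and linearly interpolates trajectories onto a
#' regular grid. A clone first observed at time t is given an emergence point
#' at frequency 0 midway between the previous observation and t (standard
#' fish-plot convention).
#'
#' @param table Data frame with columns `time`, `clone`, `frequency`; one
#'   tumor, one row per (time, clone).
#' @param parents Named character vector mapping each clone to its parent
#'   clone; the root clone maps to `NA` (or is absent from the map).
#' @param grid_points Number of interpolation points across the observed time
#'   range (default 50).
#' @param tol Nesting tolerance (default 1e-6).
#' @return An object of class `fishplot_data`: list with `times` (observed),
#'   `grid`, `trajectories` (tibble clone x grid frequency), `parents`.
#' @export
fishplot_data <- function(table, parents, grid_points = 50, tol = 1e-6) {
  check_columns(table, c("time", "clone", "frequency"), "table")
  table <- as_tibble(table)
  times <- sort(unique(table$time))
  clones <- unique(table$clone)

  # complete the (time, clone) grid with zeros
  full <- tidyr::expand_grid(time = times, clone = clones) |>
    left_join(table, by = c("time", "clone")) |>
    mutate(frequency = dplyr::coalesce(.data$frequency, 0))

  # nesting validation: children must fit inside their parent at every time
  for (tp in times) {
    ft <- full |> filter(.data$time == tp)
    f <- setNames(ft$frequency, ft$clone)
    for (p in unique(stats::na.omit(parents[clones]))) {
      kids <- names(parents)[!is.na(parents) & parents == p]
      kids <- intersect(kids, clones)
      if (length(kids) == 0) next
      child_sum <- sum(f[kids], na.rm = TRUE)
      parent_f <- if (p %in% names(f)) f[[p]] else 0
      if (child_sum > parent_f + tol) {
        abort(sprintf(
          "Nesting violation at time %s: children of clone %s sum to %.3f > parent frequency %.3f.",
          format(tp), p, child_sum, parent_f
        ))
      }
    }
    if (any(f < -tol | f > 1 + tol)) {
      abort(sprintf("Frequencies outside [0, 1] at time %s.", format(tp)))
    }
  }

  grid <- if (length(times) == 1) {
    times
  } else {
    seq(min(times), max(times), length.out = grid_points)
  }
  traj <- purrr::map_dfr(clones, function(cl) {
    obs <- full |> filter(.data$clone == cl) |> arrange(.data$time)
    tt <- obs$time
    ff <- obs$frequency
    # emergence midpoint: a clone appearing at its first nonzero observation
    # is pinned to zero midway since the previous time point
    nz <- which(ff > 0)
    if (length(nz) > 0 && nz[1] > 1) {
      i <- nz[1]
      if (ff[i - 1] == 0) {
        tt <- append(tt, (tt[i - 1] + tt[i]) / 2, after = i - 1)
        ff <- append(ff, 0, after = i - 1)
      }
    }
    y <- if (length(tt) == 1) {
      rep(ff, length(grid))
    } else {
      stats::approx(tt, ff, xout = grid, rule = 2)$y
    }
    tibble(clone = cl, time = grid, frequency = pmax(y, 0))
  })
  structure(
    list(times = times, grid = grid, trajectories = traj,
         parents = parents),
    class = "fishplot_data"
  )
}

#' @export
print.fishplot_data <- function(x, ...) {
  cat(sprintf(
    "fishplot_data: %d clone(s) over %d time point(s) (grid of %d)\n",
    length(unique(x$trajectories$clone)), length(x$times), length(x$grid)
  ))
  invisible(x)
}

#' Write fish-plot data as JSON
#'
#' Serialises the interpolation grid, per-clone frequency series and parent
#' map for downstream plotting tools.
#'
#' @param x A `fishplot_data` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fishplot_json <- function(x, path) {
  stopifnot(inherits(x, "fishplot_data"))
  series <- split(x$trajectories$frequency, x$trajectories$clone)
  payload <- list(
    grid = x$grid,
    observed_times = x$times,
    clones = names(series),
    frequencies = series,
    parents = as.list(x$parents)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
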