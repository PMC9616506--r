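#' Single-cell bin-by-cell copy-number container
#'
#' Bundles an integer copy-state matrix (bins in rows, cells in columns) with
#' its genomic bin scaffold and the expected baseline ploidy per cell.
#' Bins follow the BED convention (0-based half-open) and must be sorted by
#' chromosome then start with no intra-chromosome overlap.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end` at ~1-Mb
#'   resolution.
#' @param copy_state Integer matrix, `nrow(bins)` rows; column names are cell
#'   identifiers.
#' @param baseline_ploidy Expected copy number in unaberrated bins: a single
#'   integer (default 2) or one per cell (e.g. 4 for whole-genome-duplicated
#'   cells).
#' @return An object of class `cell_bin_matrix`.
#' @export
cell_bin_matrix <- function(bins, copy_state, baseline_ploidy = 2L) {
  bins <- as_tibble(bins)
  check_columns(bins, c("chrom", "start", "end"), "bins")
  copy_state <- as.matrix(copy_state)
  if (nrow(copy_state) != nrow(bins)) {
    abort("`copy_state` must have one row per bin.")
  }
  if (is.null(colnames(copy_state))) {
    abort("`copy_state` must have cell identifiers as column names.")
  }
  if (any(copy_state < 0)) abort("Copy states must be non-negative.")
  # sorted, non-overlapping bins within each chromosome
  by_chr <- split(seq_len(nrow(bins)), bins$chrom)
  for (idx in by_chr) {
    s <- bins$start[idx]
    e <- bins$end[idx]
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)])) {
      abort("Bins must be sorted and non-overlapping within each chromosome.")
    }
  }
  nc <- ncol(copy_state)
  if (length(baseline_ploidy) == 1) {
    baseline_ploidy <- rep(as.integer(baseline_ploidy), nc)
  }
  if (length(baseline_ploidy) != nc || any(baseline_ploidy < 1)) {
    abort("`baseline_ploidy` must be a positive integer, one value or one per cell.")
  }
  structure(
    list(
      bins = bins, copy_state = copy_state,
      baseline_ploidy = setNames(as.integer(baseline_ploidy),
                                 colnames(copy_state))
    ),
    class = "cell_bin_matrix"
  )
}

#' @export
print.cell_bin_matrix <- function(x, ...) {
  cat(sprintf(
    "cell_bin_matrix: %d bins x %d cells on %d chromosome(s)\n",
    nrow(x$bins), ncol(x$copy_state), length(unique(x$bins$chrom))
  ))
  invisible(x)
}

# Tolerant cell grouping: connected components of the pairwise graph where
# two cells match if their event sets pair one-to-one (same chrom, direction
# and state; reciprocal span overlap >= 50%). Greedy pairing is adequate
# because per-cell events are disjoint genomic intervals.
overlap_cell_groups <- function(events_per_cell) {
  cells <- sort(names(events_per_cell))
  n <- length(cells)
  sets_match <- function(a, b) {
    if (nrow(a) != nrow(b)) return(FALSE)
    if (nrow(a) == 0) return(TRUE)
    used <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(a))) {
      hit <- FALSE
      for (j in seq_len(nrow(b))) {
        if (used[j]) next
        if (a$chrom[i] == b$chrom[j] &&
            a$direction[i] == b$direction[j] &&
            a$copy_state[i] == b$copy_state[j]) {
          ov <- min(a$end_bin[i], b$end_bin[j]) -
            max(a$start_bin[i], b$start_bin[j]) + 1L
          la <- a$end_bin[i] - a$start_bin[i] + 1L
          lb <- b$end_bin[j] - b$start_bin[j] + 1L
          if (ov >= 0.5 * la && ov >= 0.5 * lb) {
            used[j] <- TRUE
            hit <- TRUE
            break
          }
        }
      }
      if (!hit) return(FALSE)
    }
    TRUE
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (sets_match(events_per_cell[[cells[i]]],
                     events_per_cell[[cells[j]]])) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(cells, roots))
}

# Close short interruptions: a gap of at most `max_gap` bins flanked on both
# sides by runs of the same state is overwritten with that state. Applied
# iteratively until stable so chains of near-adjacent runs coalesce.
fill_state_gaps <- function(states, max_gap) {
  repeat {
    r <- rle(states)
    if (length(r$values) < 3) return(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (k in 2:(length(r$values) - 1)) {
      if (r$lengths[k] <= max_gap &&
          r$values[k - 1] == r$values[k + 1] &&
          r$values[k] != r$values[k - 1]) {
        states[starts[k]:ends[k]] <- r$values[k - 1]
        changed <- TRUE
        break
      }
    }
    if (!changed) return(states)
  }
}

# canonical identity key for an event (comparison by chrom, span,
# direction and copy state)
event_key <- function(events) {
  if (nrow(events) == 0) return(character(0))
  sprintf(
    "%s:%d-%d:%s:%d",
    events$chrom, events$start_bin, events$end_bin,
    as.character(events$direction), events$copy_state
  )
}

#' Call copy-number events in one cell from its bin profile
#'
#' Scans a cell's integer copy-state profile for maximal runs of consecutive
#' same-chromosome bins deviating from the baseline ploidy at a constant
#' state. Runs at least `min_imbalance_bins` long are emitted as imbalances
#' (gain or loss); runs reaching `amplification_state_threshold` copies are
#' high-grade amplifications and need only `min_amplification_bins` bins.
#' A run qualifying for both grades is emitted once, as a high-grade
#' amplification. Shorter runs are discarded; runs never cross chromosome
#' boundaries; a single dissenting bin breaks a run.
#'
#' @param mat A [cell_bin_matrix()].
#' @param cell Cell identifier (a column of the matrix).
#' @param min_imbalance_bins Minimum run length for an ordinary imbalance
#'   (default 5 consecutive 1-Mb bins).
#' @param min_amplification_bins Minimum run length for a high-grade
#'   amplification (default 2 consecutive 1-Mb bins).
#' @param amplification_state_threshold Copy state at or above which a run
#'   counts as high-grade amplification; default `baseline_ploidy + 3`
#'   (i.e. >= 5 copies on a diploid background).
#' @param max_gap_bins Gap tolerance for noisy profiles: up to this many
#'   consecutive dissenting bins between two runs of the same state are
#'   absorbed into one run (default 0 — strict, any dissenting bin breaks a
#'   run).
#' @return A tibble of events: `chrom`, `start_bin`, `end_bin` (inclusive
#'   row indices into `mat$bins`), `start`, `end` (bp, BED convention),
#'   `direction` (gain/loss), `copy_state`, `grade`, `length_bins`.
#' @export
call_cell_events <- function(mat, cell,
                             min_imbalance_bins = 5L,
                             min_amplification_bins = 2L,
                             amplification_state_threshold = NULL,
                             max_gap_bins = 0L) {
  stopifnot(inherits(mat, "cell_bin_matrix"))
  if (!cell %in% colnames(mat$copy_state)) {
    abort(sprintf("Unknown cell `%s`.", cell))
  }
  baseline <- mat$baseline_ploidy[[cell]]
  amp_thr <- amplification_state_threshold %||% (baseline + 3L)
  profile <- mat$copy_state[, cell]

  out <- vector("list", 0)
  for (ch in unique(mat$bins$chrom)) {
    idx <- which(mat$bins$chrom == ch)
    states <- profile[idx]
    if (max_gap_bins > 0) states <- fill_state_gaps(states, max_gap_bins)
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      st <- r$values[k]
      len <- r$lengths[k]
      if (st == baseline) next
      is_amp <- st >= amp_thr && len >= min_amplification_bins
      is_imb <- len >= min_imbalance_bins
      if (!is_amp && !is_imb) next
      i0 <- idx[starts[k]]
      i1 <- idx[ends[k]]
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start_bin = i0, end_bin = i1,
        start = mat$bins$start[i0], end = mat$bins$end[i1],
        direction = if (st > baseline) "gain" else "loss",
        copy_state = as.integer(st),
        grade = if (is_amp) "high_grade_amplification" else "imbalance",
        length_bins = as.integer(len)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      chrom = character(0), start_bin = integer(0), end_bin = integer(0),
      start = numeric(0), end = numeric(0), direction = character(0),
      copy_state = integer(0), grade = character(0), length_bins = integer(0)
    ))
  }
  bind_rows(out) |> arrange(.data$start_bin)
}

#' Call events for every cell in a matrix
#'
#' @inheritParams call_cell_events
#' @return A named list (one tibble of events per cell), suitable for
#'   [group_cells_into_clones()].
#' @export
call_all_cells <- function(mat, min_imbalance_bins = 5L,
                           min_amplification_bins = 2L,
                           amplification_state_threshold = NULL,
                           max_gap_bins = 0L) {
  cells <- colnames(mat$copy_state)
  setNames(
    purrr::map(cells, function(cl) {
      call_cell_events(mat, cl, min_imbalance_bins, min_amplification_bins,
                       amplification_state_threshold, max_gap_bins)
    }),
    cells
  )
}

#' Group cells into clones by exact event-set identity
#'
#' Cells carrying identical event sets (events compared by chromosome, bin
#' span, direction and copy state) form a clone. Clones are labelled
#' deterministically `C1`, `C2`, ... by decreasing cell count, ties broken by
#' the lexicographically smallest member cell id; event-free cells form a
#' designated `"baseline"` clone. Single-cell clones are flagged.
#'
#' @param events_per_cell Named list mapping each cell id to its event tibble
#'   (as from [call_all_cells()]).
#' @param match_mode `"exact"` (default): cells share a clone iff their event
#'   sets are identical (chrom, bin span, direction, copy state).
#'   `"overlap"`: tolerant matching for noisy profiles — two cells share a
#'   clone when their event sets match one-to-one, events pairing by equal
#'   chromosome, direction and copy state with reciprocal span overlap of at
#'   least 50%; cells are then grouped by the connected components of the
#'   pairwise-match graph.
#' @return An object of class `clone_assignment`: list with `cells` (tibble
#'   cell/clone), `clones` (tibble clone/n_cells/frequency/is_singleton),
#'   `clone_events` (named list of event tibbles per clone) and `n_cells`.
#' @export
group_cells_into_clones <- function(events_per_cell,
                                    match_mode = c("exact", "overlap")) {
  match_mode <- match.arg(match_mode)
  if (length(events_per_cell) == 0) {
    abort("At least one cell is required.")
  }
  if (is.null(names(events_per_cell))) {
    abort("`events_per_cell` must be a named list (cell identifiers).")
  }
  if (match_mode == "exact") {
    keysets <- purrr::map(events_per_cell, function(ev) sort(event_key(ev)))
    sig <- purrr::map_chr(keysets, function(k) paste(k, collapse = "|"))
    groups <- split(names(sig), sig)
  } else {
    groups <- overlap_cell_groups(events_per_cell)
  }

  # deterministic labelling: by decreasing size, ties by smallest member id
  first_cell <- purrr::map_chr(groups, function(cs) sort(cs)[1])
  ord <- order(-lengths(groups), first_cell)
  groups <- groups[ord]
  is_base <- purrr::map_lgl(groups, function(cs) {
    nrow(events_per_cell[[sort(cs)[1]]]) == 0
  })
  labels <- character(length(groups))
  k <- 0L
  for (i in seq_along(groups)) {
    if (is_base[i]) {
      labels[i] <- "baseline"
    } else {
      k <- k + 1L
      labels[i] <- sprintf("C%d", k)
    }
  }
  n_total <- length(events_per_cell)
  cells_tbl <- purrr::map2_dfr(labels, groups, function(lab, cs) {
    tibble(cell = sort(cs), clone = lab)
  })
  sizes <- unname(lengths(groups))
  clones_tbl <- tibble(
    clone = labels,
    n_cells = sizes,
    frequency = sizes / n_total,
    is_singleton = sizes == 1L
  )
  clone_events <- setNames(
    purrr::map(groups, function(cs) events_per_cell[[cs[1]]]),
    labels
  )
  structure(
    list(
      cells = cells_tbl, clones = clones_tbl,
      clone_events = clone_events, n_cells = n_total
    ),
    class = "clone_assignment"
  )
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat(sprintf(
    "clone_assignment: %d cells in %d clone(s)\n", x$n_cells,
    nrow(x$clones)
  ))
  print(x$clones)
  invisible(x)
}

#' Build a binary event matrix from a clone assignment
#'
#' Rows are the union of called events ordered by genomic position; columns
#' are clones (default) or individual cells. Entries are binary presence.
#' Clone columns carry cell-count weights (cells weigh 1), so the weights
#' always sum to the number of cells.
#'
#' @param assignment A `clone_assignment` from [group_cells_into_clones()].
#' @param columns `"clones"` or `"cells"`.
#' @return An object of class `event_matrix`: list with `matrix` (0/1
#'   integer, events x columns), `events` (tibble describing the rows),
#'   `weights` (named numeric per column) and `columns`.
#' @export
build_event_matrix <- function(assignment, columns = c("clones", "cells")) {
  stopifnot(inherits(assignment, "clone_assignment"))
  columns <- match.arg(columns)
  all_events <- bind_rows(assignment$clone_events) |> distinct()
  if (nrow(all_events) > 0) {
    all_events <- all_events |>
      arrange(
        match(.data$chrom, unique(genome_bins()$chrom)),
        .data$chrom, .data$start_bin, .data$end_bin, .data$direction,
        .data$copy_state
      )
  }
  keys <- event_key(all_events)

  if (columns == "clones") {
    ids <- assignment$clones$clone
    wts <- setNames(as.numeric(assignment$clones$n_cells), ids)
    presence <- purrr::map(ids, function(cl) {
      as.integer(keys %in% event_key(assignment$clone_events[[cl]]))
    })
  } else {
    ids <- sort(assignment$cells$cell)
    wts <- setNames(rep(1, length(ids)), ids)
    clone_of <- setNames(assignment$cells$clone, assignment$cells$cell)
    presence <- purrr::map(ids, function(cl) {
      as.integer(keys %in% event_key(assignment$clone_events[[clone_of[[cl]]]]))
    })
  }
  m <- matrix(unlist(presence, use.names = FALSE),
    nrow = length(keys), ncol = length(ids),
    dimnames = list(keys, ids)
  )
  structure(
    list(matrix = m, events = all_events, weights = wts, columns = columns),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf(
    "event_matrix: %d event(s) x %d %s\n", nrow(x$matrix), ncol(x$matrix),
    x$columns
  ))
  invisible(x)
}

#' Construct an event matrix directly from per-column event sets
#'
#' Convenience constructor for bulk samples or externally defined clones:
#' takes a named list of character event identifiers per column and returns
#' the binary `event_matrix` over their union (rows sorted lexicographically,
#' columns in input order).
#'
#' @param event_sets Named list of character vectors.
#' @param weights Optional numeric column weights (default 1 each).
#' @return An `event_matrix`.
#' @export
event_matrix_from_sets <- function(event_sets, weights = NULL) {
  if (length(event_sets) == 0 || is.null(names(event_sets))) {
    abort("`event_sets` must be a non-empty named list.")
  }
  keys <- sort(unique(unlist(event_sets, use.names = FALSE)))
  ids <- names(event_sets)
  m <- vapply(event_sets, function(s) as.integer(keys %in% s),
    integer(length(keys))
  )
  m <- matrix(m, nrow = length(keys), dimnames = list(keys, ids))
  wts <- weights %||% setNames(rep(1, length(ids)), ids)
  structure(
    list(matrix = m, events = tibble(event = keys), weights = wts,
         columns = "sets"),
    class = "event_matrix"
  )
}
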