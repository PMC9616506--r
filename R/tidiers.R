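# broom-style tidiers

#' Tidy a purity estimate
#'
#' @param x A `purity_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `sample_id`, `tcf`, `sd_msf`, `interval_low`,
#'   `interval_high`, `n_clonal`.
#' @export
tidy.purity_estimate <- function(x, ...) {
  tibble(
    sample_id = x$sample_id, tcf = x$tcf, sd_msf = x$sd_msf,
    interval_low = x$clonal_msf_interval[1],
    interval_high = x$clonal_msf_interval[2],
    n_clonal = x$n_clonal
  )
}

#' Tidy a clone tree: one row per edge event change
#'
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @return The per-edge event assignment tibble (`parent`, `child`, `event`,
#'   `change`).
#' @export
tidy.clone_tree <- function(x, ...) {
  x$edge_events
}

#' One-row summary of a clone tree
#'
#' @param x A `clone_tree`.
#' @param ... Unused.
#' @return Tibble with `n_leaves`, `n_events`, `score`, `n_homoplasic`
#'   (events needing more than one change), `perfect_phylogeny`.
#' @export
glance.clone_tree <- function(x, ...) {
  tibble(
    n_leaves = x$n_leaves,
    n_events = length(x$per_event_changes),
    score = x$score,
    n_homoplasic = sum(x$per_event_changes >= 2),
    perfect_phylogeny = x$score == length(x$per_event_changes)
  )
}

#' Tidy a survival filter result
#'
#' @param x A `survival_filter`.
#' @param ... Unused.
#' @return The per-gene results tibble.
#' @export
tidy.survival_filter <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a survival filter result
#'
#' @param x A `survival_filter`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_retained`, `fdr_threshold`,
#'   `min_q_value`.
#' @export
glance.survival_filter <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_retained = sum(x$retained),
    fdr_threshold = attr(x, "fdr_threshold"),
    min_q_value = min(x$q_value)
  )
}

#' Tidy a clone assignment: one row per clone
#'
#' @param x A `clone_assignment`.
#' @param ... Unused.
#' @return The clone summary tibble (`clone`, `n_cells`, `frequency`,
#'   `is_singleton`).
#' @export
tidy.clone_assignment <- function(x, ...) {
  x$clones
}
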