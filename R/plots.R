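# ggplot2 visualisations for the main result types

#' Fish plot of clone frequencies over time
#'
#' Symmetric stacked-area rendering of the interpolated clone trajectories:
#' each clone's band height equals its frequency, stacked in clone order and
#' centered vertically. The proper nested fish-plot layout (children drawn
#' inside parents) is left to dedicated renderers; this view shows the same
#' validated frequency series.
#'
#' @param object A `fishplot_data`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fishplot_data <- function(object, ...) {
  tr <- object$trajectories
  ggplot2::ggplot(tr, ggplot2::aes(
    x = .data$time, y = .data$frequency, fill = .data$clone
  )) +
    ggplot2::geom_area(position = "stack", color = "grey30",
                       linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$times, linetype = "dotted",
                        color = "grey50") +
    ggplot2::labs(x = "Time (days)", y = "Clone frequency",
                  fill = "Clone") +
    ggplot2::theme_minimal()
}

#' Plot MSF against assigned MCF for clonality calls
#'
#' @param calls Output of [bulk_clonality()] (needs `msf`, `mcf`, `status`).
#' @return A ggplot object.
#' @export
plot_clonality_calls <- function(calls) {
  check_columns(calls, c("msf", "mcf", "status"), "calls")
  ggplot2::ggplot(calls, ggplot2::aes(
    x = .data$msf, y = .data$mcf, color = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::labs(x = "Mutated sample fraction",
                  y = "Mutated clone fraction", color = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a single-cell copy-state matrix
#'
#' @param object A `cell_bin_matrix`.
#' @param ... Unused.
#' @return A ggplot object (bins on x, cells on y, fill = copy state).
#' @export
autoplot.cell_bin_matrix <- function(object, ...) {
  df <- as_tibble(object$copy_state) |>
    mutate(bin = dplyr::row_number()) |>
    tidyr::pivot_longer(-"bin", names_to = "cell", values_to = "copy")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin, y = .data$cell, fill = factor(.data$copy)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(name = "Copies") +
    ggplot2::labs(x = "1-Mb bin", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-gene survival-filter results
#'
#' Log-rank significance per signature gene: -log10 q-value against the
#' hazard direction of the high-expression arm, with the retention cutoff
#' marked.
#'
#' @param object A `survival_filter` (from [integrate_signature()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_filter <- function(object, ...) {
  thr <- attr(object, "fdr_threshold") %||% 0.05
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$direction, y = -log10(.data$q_value),
    color = .data$retained
  )) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::labs(x = "Worse-survival arm", y = "-log10 q-value",
                  color = "Retained") +
    ggplot2::theme_minimal()
}

#' Plot volume trajectories colored by response call
#'
#' @param volumes Long table with `mouse_id`, `day`, `volume`.
#' @param calls Optional per-mouse calls (from [classify_cohort()]) to color
#'   by `response`.
#' @return A ggplot object.
#' @export
plot_volume_series <- function(volumes, calls = NULL) {
  check_columns(volumes, c("mouse_id", "day", "volume"), "volumes")
  df <- as_tibble(volumes)
  if (!is.null(calls)) {
    df <- left_join(df, calls |> select("mouse_id", "response"),
                    by = "mouse_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$day, y = .data$volume, group = .data$mouse_id,
      color = .data$response
    ))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$day, y = .data$volume, group = .data$mouse_id
    ))
  }
  p +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Day", y = expression(Volume ~ (mm^3))) +
    ggplot2::theme_minimal()
}
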