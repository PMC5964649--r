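#' Plot inner and outer cell counts over time
#'
#' @param counts A [counts_by_type()] result (optionally with an
#'   `embryo_id` column for multi-embryo panels).
#' @param time_col Time axis column (default `"time_na"` when present,
#'   else `"time_hp"`).
#' @return A ggplot object.
#' @export
plot_cell_counts <- function(counts, time_col = NULL) {
  time_col <- time_col %||%
    if ("time_na" %in% names(counts)) "time_na" else "time_hp"
  long <- counts |>
    tidyr::pivot_longer(c("n_inner", "n_outer"), names_to = "type",
                        values_to = "count") |>
    mutate(type = sub("^n_", "", .data$type))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data[[time_col]], y = .data$count, colour = .data$type)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(
      values = c(inner = "#E6B33C", outer = "#2AA198")) +
    ggplot2::labs(x = if (time_col == "time_na") "time (n.a.)" else
      "time (h post fertilization/activation)",
      y = "cell count", colour = NULL) +
    ggplot2::theme_minimal()
  if ("embryo_id" %in% names(counts)) {
    p <- p + ggplot2::facet_wrap(~embryo_id)
  }
  p
}

#' @export
autoplot.bt_counts <- function(object, ...) plot_cell_counts(object, ...)

#' Plot a binned asymmetric-division profile (OAD/IAD)
#'
#' @param binned An [asymmetric_division_proportion()] result.
#' @return A ggplot object.
#' @export
plot_division_profile <- function(binned) {
  ggplot2::ggplot(filter(binned, !.data$empty), ggplot2::aes(
    x = .data$bin_mid, y = .data$proportion)) +
    ggplot2::geom_col(width = binned$bin_hi[1] - binned$bin_lo[1],
                      fill = "#2AA198") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (n.a.)",
                  y = "proportion of asymmetric divisions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bt_binned <- function(object, ...) plot_division_profile(object, ...)

#' Plot coefficient-of-variation series
#'
#' @param cv A [coefficient_of_variation()] result (optionally with a
#'   `condition` column from [condition_comparison()]).
#' @return A ggplot object.
#' @export
plot_cv <- function(cv) {
  p <- ggplot2::ggplot(cv, ggplot2::aes(
    x = .data$time_na, y = .data$cv, colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(inner = "#E6B33C", outer = "#2AA198")) +
    ggplot2::labs(x = "time (n.a.)", y = "coefficient of variation",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("condition" %in% names(cv)) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' @export
autoplot.bt_cv <- function(object, ...) plot_cv(object, ...)

#' Plot an embryo volume series with its detected collapse
#'
#' @param volumes A [hull_volume_series()] result.
#' @param collapse Optional [detect_first_collapse()] result to mark.
#' @return A ggplot object.
#' @export
plot_volume_series <- function(volumes, collapse = NULL) {
  p <- ggplot2::ggplot(volumes, ggplot2::aes(
    x = .data$time_hp, y = .data$volume / 1e6)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (h post fertilization/activation)",
                  y = expression(hull ~ volume ~ (10^6 ~ mu * m^3))) +
    ggplot2::theme_minimal()
  if (!is.null(collapse)) {
    p <- p + ggplot2::geom_vline(xintercept = collapse$time_hp,
                                 linetype = "dashed", colour = "#B2182B")
  }
  p
}
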