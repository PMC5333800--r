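# ggplot2 views of the survey's result types.

#' Plot the df distribution of a record set
#'
#' Histogram of degrees of freedom, optionally split by the recomputed
#' significance flag, zoomed to a quantile of the right tail for
#' readability (all records are still counted).
#'
#' @param records A records tibble (after [estimate_effects()] if
#'   `by_significance`).
#' @param by_significance Facet by the `significant` flag.
#' @param zoom Upper quantile of df shown.
#' @return A ggplot object.
#' @export
plot_df_distribution <- function(records, by_significance = FALSE,
                                 zoom = 0.99) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$df)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::coord_cartesian(
      xlim = c(0, quantile(records$df, zoom, type = 7))) +
    ggplot2::labs(x = "degrees of freedom", y = "records") +
    ggplot2::theme_minimal()
  if (by_significance) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$significant),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot effect-size distributions by significance
#'
#' Density of the mixture effect size for significant and nonsignificant
#' records — the split that makes selection visible.
#'
#' @param effects Output of [estimate_effects()].
#' @param zoom Upper quantile of D shown.
#' @return A ggplot object.
#' @export
plot_effect_distribution <- function(effects, zoom = 0.99) {
  ggplot2::ggplot(effects, ggplot2::aes(x = .data$d_mixture,
                                        fill = .data$significant)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::coord_cartesian(
      xlim = c(0, quantile(effects$d_mixture, zoom, type = 7))) +
    ggplot2::labs(x = "effect size D", y = "density",
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' Plot cumulative power curves by group
#'
#' Complementary cumulative distribution of power ("fraction of records
#' with at least this much power"), one curve per group, for a chosen
#' benchmark effect.
#'
#' @param records_power Output of [add_power()], with an optional grouping
#'   column.
#' @param power_col Which power column to plot.
#' @param group Optional name of a grouping column (e.g. `"subfield"`).
#' @return A ggplot object.
#' @export
plot_power_cumulative <- function(records_power,
                                  power_col = "power_medium",
                                  group = NULL) {
  grid <- seq(0, 1, by = 0.01)
  dat <- if (is.null(group)) {
    dplyr::mutate(cumulative_distribution(records_power[[power_col]], grid),
                  group = "all")
  } else {
    records_power |>
      dplyr::group_by(group = .data[[group]]) |>
      dplyr::reframe(cumulative_distribution(.data[[power_col]], grid))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$threshold, y = .data$fraction,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("power (%s)", power_col),
                  y = "fraction of records with at least this power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot expected-FRP curves over prestudy odds
#'
#' One curve per bias value, odds on a log10 axis — the FRP-versus-odds
#' family showing how quickly false reports dominate as prestudy odds or
#' bias grow.
#'
#' @param curves Output of [frp_curves()].
#' @return A ggplot object.
#' @export
plot_frp_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$odds, y = .data$frp,
                                       colour = factor(.data$bias))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "prestudy H0:H1 odds", y = "expected FRP",
                  colour = "bias u") +
    ggplot2::theme_minimal()
}
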