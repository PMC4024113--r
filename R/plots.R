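#' Plot the six-month retention surface
#'
#' Reproduces the retention-surface figure: percentage of patients alive and
#' active in care at 6 months (y-axis) against the proportional reduction in
#' quarterly mortality (x-axis), one line per LTFU-reduction level, faceted by
#' BMI stratum. The y-intercept of the lowest line is the historical
#' retention.
#'
#' @param surface a `retention_surface` tibble from [retention_surface()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_retention_surface <- function(surface, ...) {
  ggplot2::ggplot(
    surface,
    ggplot2::aes(
      x = .data$r_mort, y = .data$pct_alive,
      colour = factor(.data$r_ltfu), group = factor(.data$r_ltfu)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "Reduction in quarterly mortality",
      y = "Alive and in care at 6 months (%)",
      colour = "Reduction in\nquarterly LTFU"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_retention_surface
#' @param object a `retention_surface` tibble.
#' @method autoplot retention_surface
#' @export
autoplot.retention_surface <- function(object, ...) plot_retention_surface(object, ...)

#' Plot parity frontiers
#'
#' Mortality/LTFU reduction combinations at which a supplement of a given
#' quarterly price exactly maintains cost-effectiveness parity with ART
#' alone; combinations beyond a line are strictly more cost-effective.
#'
#' @param frontier a `parity_frontier` tibble (possibly several prices bound
#'   together) from [parity_frontier()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_parity_frontier <- function(frontier, ...) {
  ggplot2::ggplot(
    frontier,
    ggplot2::aes(
      x = .data$r_mort, y = .data$r_ltfu,
      colour = factor(round(.data$supplement_cost, 2)),
      group = factor(.data$supplement_cost)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(
      x = "Reduction in quarterly mortality",
      y = "Reduction in quarterly LTFU",
      colour = "Quarterly supplement\ncost (USD)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_parity_frontier
#' @param object a `parity_frontier` tibble.
#' @method autoplot parity_frontier
#' @export
autoplot.parity_frontier <- function(object, ...) plot_parity_frontier(object, ...)

#' Plot the ART-cost sensitivity sweep
#'
#' Maximum cost-effective quarterly supplement price as a function of the
#' annual ART programme cost, one line per BMI stratum.
#'
#' @param sweep an `art_cost_sweep` tibble from [art_cost_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_art_cost_sweep <- function(sweep, ...) {
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(x = .data$annual_art_cost, y = .data$s_star, colour = .data$stratum)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Annual ART programme cost (USD per patient-year)",
      y = "Maximum quarterly supplement cost (USD)",
      colour = "BMI stratum"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_art_cost_sweep
#' @param object an `art_cost_sweep` tibble.
#' @method autoplot art_cost_sweep
#' @export
autoplot.art_cost_sweep <- function(object, ...) plot_art_cost_sweep(object, ...)

#' @rdname fit_cea
#' @param object a `cea_fit` object (for `autoplot`).
#' @method autoplot cea_fit
#' @export
autoplot.cea_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$scenarios,
    cols = -c("scenario", "r_mort", "r_ltfu"),
    names_to = "stratum", values_to = "s_star"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$stratum, y = .data$s_star, fill = .data$scenario)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "BMI stratum (kg/m²)",
      y = "Maximum quarterly supplement cost (USD)",
      fill = "Effect scenario"
    ) +
    ggplot2::theme_minimal()
}
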