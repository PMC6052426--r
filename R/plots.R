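## ggplot2 presentations of the result objects.

#' @describeIn run_cohort Stacked state-occupancy plot of a cohort trace.
#' @param object A `vte_trace` object.
#' @param ... Unused.
#' @export
autoplot.vte_trace <- function(object, ...) {
  states <- c("on_treatment_ivte", "on_treatment_rvte", "off_treatment",
              "rvte", "crnmb", "non_ich_mb", "ich", "death")
  long <- tidyr::pivot_longer(object$trace[, c("cycle", states)],
                              dplyr::all_of(states),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = states)
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (months)", y = "Cohort fraction",
                  fill = NULL,
                  title = paste0("Cohort trace, ", object$arm, " arm")) +
    ggplot2::theme_minimal()
}

#' @describeIn one_way_dsa Tornado diagram of the top one-way drivers.
#' @param object A `vte_tornado` tibble.
#' @param top Number of parameters shown.
#' @param ... Unused.
#' @export
autoplot.vte_tornado <- function(object, top = 10, ...) {
  base_nmb <- attr(object, "nmb_base")
  d <- utils::head(object, top)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$nmb_low, xend = .data$nmb_high,
                   y = .data$label, yend = .data$label),
      linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_nmb, linetype = 2) +
    ggplot2::labs(x = "Net monetary benefit (£)", y = NULL,
                  title = "One-way sensitivity of the NMB") +
    ggplot2::theme_minimal()
}

#' @describeIn run_psa Incremental cost-effectiveness plane of the PSA
#'   draws.
#' @param object A `vte_psa` object.
#' @export
autoplot.vte_psa <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(.data$d_qaly, .data$d_cost,
                               colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = object$summary$wtp, intercept = 0,
                         colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental costs (£)",
                  colour = NULL,
                  title = "Cost-effectiveness plane, edoxaban vs. warfarin") +
    ggplot2::theme_minimal()
}

#' @describeIn ceac Cost-effectiveness acceptability curve plot.
#' @param object A `vte_ceac` tibble.
#' @param ... Unused.
#' @export
autoplot.vte_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda, .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (£/QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
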