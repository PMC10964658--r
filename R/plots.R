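#' Plot state occupancy over time
#'
#' Stacked-area plot of the cohort trace: fraction of the cohort in each
#' health state by years since the procedure.
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  long <- tidyr::pivot_longer(as_tibble(trace)[c("years", STATES)],
                              -"years", names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = rev(STATES),
                       labels = rev(c("Alive and well", "Treated AF",
                                      "Disabling stroke", "Dead")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$years, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "Years since procedure", y = "Fraction of cohort",
                  fill = NULL,
                  title = sprintf("Cohort trace (%s)", toupper(attr(trace, "arm")))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cea_trace <- function(object, ...) plot_trace(object)

#' Cost-effectiveness plane from PSA draws
#'
#' Scatter of incremental QALYs against incremental costs per draw, with
#' the willingness-to-pay threshold line.
#'
#' @param psa A `cea_psa` tibble.
#' @param lambda Threshold line slope (Euros/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, lambda = attr(psa, "lambda") %||% 50000) {
  ggplot2::ggplot(as_tibble(psa),
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = lambda, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: %s EUR/QALY",
                                     format(lambda, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cea_psa <- function(object, ...) plot_ce_plane(object, ...)

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A `cea_ceac` tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(as_tibble(curve),
                  ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cea_ceac <- function(object, ...) plot_ceac(object)

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars spanning the INMB at each parameter's low and high
#' bound, ranked by swing, around the base-case INMB.
#'
#' @param tornado A `cea_tornado` tibble from [one_way_dsa()].
#' @param top Number of parameters shown (default 12).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 12) {
  df <- utils::head(as_tibble(tornado), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low, xend = .data$inmb_high,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(tornado, "base_inmb"),
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("Incremental net monetary benefit (EUR at %s EUR/QALY)",
                              format(attr(tornado, "lambda"), big.mark = ",")),
                  y = NULL, title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cea_tornado <- function(object, ...) plot_tornado(object, ...)
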