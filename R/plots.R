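#' Cost-effectiveness plane scatter
#'
#' Plots the per-draw incremental cost against incremental effect, with the
#' willingness-to-pay threshold as a line through the origin. Points below
#' the line are cost-effective at that threshold.
#'
#' @param psa A `psa_results` object from [run_psa()].
#' @param effect `"qaly"` (discounted QALYs) or `"ly"` (undiscounted
#'   life-years).
#' @param wtp Willingness-to-pay threshold drawn as the dashed line
#'   (default the model's).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, effect = c("qaly", "ly"), wtp = psa$wtp_threshold) {
  effect <- match.arg(effect)
  d <- psa$draws
  deff <- if (effect == "qaly") d$dqaly else d$dly
  lab <- if (effect == "qaly") "Incremental QALYs" else "Incremental life-years"
  df <- tibble(deffect = deff, dcost = d$dcost)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deffect, y = .data$dcost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue4") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(
      x = lab, y = "Incremental cost (AU$)",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("Dashed line: AU$%s per unit effect", format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_curve A tibble from [ceac()] (either method).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_curve) {
  p <- ggplot2::ggplot(ceac_curve,
                       ggplot2::aes(x = .data$wtp, y = .data$prob_cost_effective))
  if ("effect" %in% names(ceac_curve)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$effect), linewidth = 0.8) +
      ggplot2::scale_colour_manual(
        values = c(qaly = "steelblue4", ly = "darkorange3"),
        labels = c(qaly = "per QALY", ly = "per life-year"), name = NULL
      )
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.8, colour = "steelblue4")
  }
  p +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::scale_x_continuous(labels = function(x) format(x, big.mark = ",")) +
    ggplot2::labs(
      x = "Willingness to pay (AU$ per unit effect)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning the ICER at each parameter's low and high
#' bound, widest at the top, with the base-case ICER as a vertical
#' reference line.
#'
#' @param owsa An `owsa_results` tibble from [run_owsa()].
#' @param top Show only the `top` widest bars (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(owsa, top = nrow(owsa)) {
  base_icer <- attr(owsa, "base_icer")
  df <- as_tibble(owsa) %>%
    arrange(desc(.data$width)) %>%
    head(top) %>%
    mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 5, colour = "steelblue4", alpha = 0.8
    ) +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::scale_x_continuous(labels = function(x) format(round(x), big.mark = ",")) +
    ggplot2::labs(
      x = "Incremental cost per QALY (AU$)", y = NULL,
      title = "One-way sensitivity analysis",
      subtitle = sprintf("Dashed line: base-case ICER AU$%s",
                         format(round(base_icer), big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psa_results <- function(object, ...) plot_ce_plane(object, ...)

#' @export
autoplot.owsa_results <- function(object, ...) plot_tornado(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
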