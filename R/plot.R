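#' Plot Levin-formula bias curves
#'
#' Four-panel display of a [bias_curves()] profile, in the layout classically
#' used for this bias analysis: absolute bias (top) and relative bias
#' (bottom), each shown both restricted to \eqn{RR_C \ge 1} (i.e.
#' \eqn{C \ge 1/RR_U}) and over the full confounding range. The adjusted
#' version of Levin's formula (causal RR plugged in) is drawn in blue, the
#' unadjusted version (crude RR plugged in) in red, and dashed horizontal
#' lines mark the analytic large-\eqn{C} limits from [bias_limits()].
#' Non-finite unadjusted relative-bias values (the true PAF crosses 0 at
#' \eqn{C = 1/RR_U}) are dropped from the drawing.
#'
#' @param object A `bias_profile` from [bias_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(bias_curves(0.5, 1.5))
#' @exportS3Method ggplot2::autoplot
autoplot.bias_profile <- function(object, ...) {
  pi <- attr(object, "pi")
  rr_u <- attr(object, "rr_u")
  lim <- attr(object, "limits")
  c_null <- 1 / rr_u

  long <- tidyr::pivot_longer(
    as_tibble(object), -"c",
    names_to = c("measure", "version"),
    names_pattern = "(rel|abs)_bias_(adj|unadj)",
    values_to = "bias"
  )
  long <- dplyr::mutate(
    long,
    measure = dplyr::recode(.data$measure, rel = "relative", abs = "absolute"),
    version = dplyr::recode(.data$version, adj = "adjusted (RR_C)",
                            unadj = "unadjusted (RR_U)")
  )
  panels <- bind_rows(
    dplyr::mutate(dplyr::filter(long, .data$measure == "absolute", .data$c >= c_null),
                  panel = "A: absolute bias, RR_C >= 1"),
    dplyr::mutate(dplyr::filter(long, .data$measure == "absolute"),
                  panel = "B: absolute bias, all RR_C"),
    dplyr::mutate(dplyr::filter(long, .data$measure == "relative", .data$c >= c_null),
                  panel = "C: relative bias, RR_C >= 1"),
    dplyr::mutate(dplyr::filter(long, .data$measure == "relative"),
                  panel = "D: relative bias, all RR_C")
  )
  panels <- dplyr::filter(panels, is.finite(.data$bias))

  limit_lines <- tibble(
    panel = c("A: absolute bias, RR_C >= 1", "B: absolute bias, all RR_C",
              "C: relative bias, RR_C >= 1", "D: relative bias, all RR_C"),
    value = c(lim$abs_limit_c_inf, lim$abs_limit_c_inf,
              lim$rel_limit_c_inf, lim$rel_limit_c_inf)
  )

  ggplot2::ggplot(panels, ggplot2::aes(x = .data$c, y = .data$bias,
                                       colour = .data$version)) +
    ggplot2::geom_hline(data = limit_lines,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~panel, nrow = 2, scales = "free") +
    ggplot2::scale_colour_manual(values = c("adjusted (RR_C)" = "#2166ac",
                                            "unadjusted (RR_U)" = "#b2182b")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "confounding ratio C = RR_C / RR_U (log scale)",
      y = "bias of Levin's formula",
      colour = "relative risk used",
      title = sprintf("Bias of Levin's formula (pi = %g, RR_U = %g)", pi, rr_u),
      subtitle = "dashed lines: analytic limits as C -> Inf"
    ) +
    ggplot2::theme_minimal()
}
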