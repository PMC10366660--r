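#' Size versus refractive-index plot
#'
#' The diagnostic view of an iNTA measurement: per-particle hydrodynamic
#' diameter against effective refractive index. Classified records are
#' colored by the EV probability; unclassified input is colored by the
#' precision gate when available.
#'
#' @param records A particle record tibble, classified or not.
#' @param ri_limits y-axis limits.
#' @return A ggplot object.
#' @export
plot_size_ri <- function(records, ri_limits = c(1.33, 1.65)) {
  required_cols(records, c("diameter_nm", "ri"), "`records`")
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$diameter_nm, y = .data$ri))
  if ("p_ev" %in% names(records)) {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(color = .data$p_ev),
                          alpha = 0.6, size = 0.8) +
      ggplot2::scale_color_gradient2(low = "#2166ac", mid = "grey70",
                                     high = "#b2182b", midpoint = 0.5,
                                     limits = c(0, 1),
                                     name = "P(EV)")
  } else if ("passes_gate" %in% names(records) &&
             !all(is.na(records$passes_gate))) {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(color = .data$passes_gate),
                          alpha = 0.6, size = 0.8) +
      ggplot2::scale_color_manual(values = c(`TRUE` = "#2c7fb8",
                                             `FALSE` = "grey60"),
                                  name = "IQR_S < cutoff")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  }
  p +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = ri_limits) +
    ggplot2::labs(x = "Diameter (nm)", y = "Effective refractive index") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.inta_classified <- function(object, ...) {
  plot_size_ri(object, ...)
}

#' Measured versus expected relative EV concentration
#'
#' Fig-2d-style mixture linearity view: one point per mixture, the identity
#' line, and the least-squares fit.
#'
#' @param mixtures A tibble with columns `expected` and `measured`
#'   (fractions in `[0, 1]`).
#' @return A ggplot object.
#' @export
plot_mixture_linearity <- function(mixtures) {
  required_cols(mixtures, c("expected", "measured"), "`mixtures`")
  ggplot2::ggplot(mixtures, ggplot2::aes(x = .data$expected,
                                         y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#b2182b", linewidth = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Expected relative EV concentration",
                  y = "Measured relative EV concentration") +
    ggplot2::theme_minimal()
}
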