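#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.fe_profile <- function(object, ...) {
  tt <- attr(object, "temperature")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy,
                                       y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "energy (reduced units)",
                  y = "free energy (reduced units)",
                  title = sprintf("Free-energy profile at T = %.3g", tt)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.heat_capacity_curve <- function(object, ...) {
  tm <- attr(object, "tm")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$temperature, y = .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = tm, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "temperature (reduced units)", y = "heat capacity",
                  title = sprintf("Cv(T), Tm = %.4g", tm)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object[object$time > 0 & object$pu > 0, ],
                  ggplot2::aes(x = .data$time, y = .data$pu)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "MC steps", y = "unfolded population",
                  title = "Unfolded-population decay") +
    ggplot2::theme_minimal()
}

#' Scatter plots of the family-level correlations
#'
#' @param object A `family_report`.
#' @param x,y Column names of `object$table` to plot (defaults: contact
#'   order against log folding rate).
#' @param ... Unused.
#' @export
autoplot.family_report <- function(object, x = "co", y = "ln_k", ...) {
  tab <- object$table[!object$table$excluded, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

#' Contact-range spectrum of a transition-state network
#'
#' @param tsn A [transition_state_network()] result.
#' @return A ggplot of contact counts by sequence separation.
#' @export
plot_tsn_spectrum <- function(tsn) {
  spec <- attr(tsn, "spectrum")
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$separation, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sequence separation |i - j|",
                  y = "contacts in the network") +
    ggplot2::theme_minimal()
}
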