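#' Heatmaps of an orientation scan
#'
#' Tilt/azimuth heatmaps of the per-orientation observables: interaction
#' energy, Boltzmann probability, ET rate, or the probability-rate product
#' that sets each orientation's contribution to the current density.
#'
#' @param object An `orientation_scan`.
#' @param value Which observable to map: `"delta_e"`, `"probability"`,
#'   `"k_et"` or `"p_times_k"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orientation_scan
#' @export
autoplot.orientation_scan <- function(object,
                                      value = c("delta_e", "probability",
                                                "k_et", "p_times_k"), ...) {
  value <- match.arg(value)
  col <- switch(value,
                delta_e = "delta_e_kj_mol", probability = "probability",
                k_et = "k_et_au", p_times_k = "p_times_k_au")
  lab <- switch(value,
                delta_e = "ΔE (kJ/mol)", probability = "P",
                k_et = "k_ET (AU)", p_times_k = "P · k_ET (AU)")
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$phi_deg, y = .data$theta_deg,
                               colour = .data[[col]])) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(name = lab) +
    ggplot2::labs(x = expression(phi ~ "(deg)"),
                  y = expression(theta ~ "(deg)"),
                  title = sprintf("Orientation landscape: %s", lab)) +
    ggplot2::theme_minimal()
}

#' Plot a current-pressure isotherm
#'
#' Coverage and total current against osmotic pressure on a log axis; the
#' current saturates at the plateau `A * J0`.
#'
#' @param isotherm A tibble from [adsorption_isotherm()] or
#'   [isotherm_report()].
#' @return A ggplot.
#' @export
plot_isotherm <- function(isotherm) {
  long <- tidyr::pivot_longer(isotherm[c("pi_au", "chi", "j_au")],
                              c("chi", "j_au"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pi_au, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(chi = "coverage χ", j_au = "current J (AU)"))) +
    ggplot2::labs(x = expression(Pi ~ "(AU)"), y = NULL) +
    ggplot2::theme_minimal()
}
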