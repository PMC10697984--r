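# ggplot2 views of the package's result types.

#' Plot a fluence spectrum
#'
#' Fluence density against energy on log-log axes.
#'
#' @param object A [fluence_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fluence_spectrum
#' @export
autoplot.fluence_spectrum <- function(object, ...) {
  df <- tibble::tibble(energy_MeV = .bin_mid(object), fluence = object$fluence)
  df <- df[df$fluence > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$energy_MeV, .data$fluence)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Electron kinetic energy (MeV)",
                  y = "Fluence density (arb. / MeV)",
                  title = sprintf("%s slowing-down spectrum", attr(object, "kind"))) +
    ggplot2::theme_minimal()
}

#' Plot an RBE calibration fit
#'
#' Calibration points with error bars and the fitted quadratic with a
#' 1-standard-uncertainty band.
#'
#' @param object An `"rbe_fit"`.
#' @param n Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rbe_fit
#' @export
autoplot.rbe_fit <- function(object, n = 200, ...) {
  grid <- exp(seq(log(object$valid_range[1]), log(object$valid_range[2]),
                  length.out = n))
  curve <- predict_rbem(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$photon_energy_MeV, .data$rbe_m)) +
    ggplot2::geom_ribbon(data = curve,
                         ggplot2::aes(ymin = .data$rbe_m - .data$std_u,
                                      ymax = .data$rbe_m + .data$std_u),
                         alpha = 0.2) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rbe_m - .data$std_u,
                                          ymax = .data$rbe_m + .data$std_u)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Photon energy (MeV)",
                  y = expression(RBE[M] ~ "(relative to " * {}^{60} * "Co)"),
                  title = "Quadratic RBE calibration") +
    ggplot2::theme_minimal()
}

#' Dose-average LET against off-axis position
#'
#' Profiles of the TEF and SE dose-average LET by position category,
#' faceted by depth, for one field or several.
#'
#' @param results Tibble from [run_let_pipeline()] or
#'   [load_published_tables()].
#' @return A ggplot.
#' @export
plot_let_profiles <- function(results) {
  long <- results |>
    dplyr::select("field_cm", "depth_cm", "position", "dose_tef", "dose_se") |>
    tidyr::pivot_longer(c("dose_tef", "dose_se"),
                        names_to = "spectrum", values_to = "dose_let") |>
    dplyr::mutate(
      spectrum = dplyr::recode(.data$spectrum, dose_tef = "TEF", dose_se = "SE"),
      position = factor(.data$position, levels = .position_levels))
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$dose_let,
                                     colour = factor(.data$field_cm),
                                     group = .data$field_cm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(spectrum ~ depth_cm, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Dose-average LET (keV/um)",
                  colour = "Field side (cm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
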