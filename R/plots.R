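#' Diagnostic plots
#'
#' `autoplot()` methods for the package's result objects: tilt histograms,
#' Lorentzian peak fits, adhesion-energy fits and topography maps.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name lamellaflex-autoplot
NULL

#' @rdname lamellaflex-autoplot
#' @method autoplot tilt_histogram
#' @export
autoplot.tilt_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = modal_tilt(object), linetype = 2) +
    ggplot2::labs(x = "tilt angle (degrees)", y = "lipids",
                  title = sprintf("Modal tilt %.1f deg (n = %d)",
                                  modal_tilt(object),
                                  attr(object, "n_lipids"))) +
    ggplot2::theme_minimal()
}

#' @rdname lamellaflex-autoplot
#' @method autoplot peak_fit
#' @export
autoplot.peak_fit <- function(object, ...) {
  d <- object$data
  hw <- object$fwhm / 2
  d$fitted <- object$amplitude * hw^2 / ((d$q - object$q0)^2 + hw^2) +
    object$background[1] + object$background[2] * (d$q - object$q0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "q (1/Å)", y = "intensity",
                  title = sprintf(
                    "q0 = %.4f 1/Å, FWHM = %.4g 1/Å (d = %.3g Å, ξ = %.3g Å)",
                    object$q0, object$fwhm, spacing_from_peak(object),
                    correlation_length_from_peak(object))) +
    ggplot2::theme_minimal()
}

#' @rdname lamellaflex-autoplot
#' @method autoplot adhesion_fit
#' @export
autoplot.adhesion_fit <- function(object, ...) {
  obs <- object$observations
  d <- tibble::tibble(
    x = sqrt(obs$strain),
    y = (obs$lambda_nm * 1e-9) / (obs$t_nm * 1e-9)^1.5)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 15, size = 2, colour = "grey30") +
    ggplot2::geom_abline(slope = object$slope_m, intercept = 0,
                         colour = "firebrick") +
    ggplot2::labs(
      x = expression(sqrt(strain)),
      y = expression(lambda / t^{3 / 2} ~ (m^{-1 / 2})),
      title = sprintf("Γ = %.3f ± %.3f J/m² (n = %d)",
                      object$gamma_hat, object$gamma_se, object$n_obs)) +
    ggplot2::theme_minimal()
}

#' @rdname lamellaflex-autoplot
#' @method autoplot topography_map
#' @export
autoplot.topography_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
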