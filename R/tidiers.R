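#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an adhesion-energy fit
#'
#' @param x An `adhesion_fit` from [fit_adhesion_energy()].
#' @param ... Unused.
#' @return One row per model term (the through-origin slope and the derived
#'   adhesion energy) with `estimate` and `std.error`.
#' @method tidy adhesion_fit
#' @export
tidy.adhesion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope_m", "gamma"),
    estimate = c(x$slope_m, x$gamma_hat),
    std.error = c(x$slope_se, x$gamma_se),
    unit = c("m^(-1/2)", "J/m^2"))
}

#' @rdname tidy.adhesion_fit
#' @method glance adhesion_fit
#' @export
glance.adhesion_fit <- function(x, ...) {
  tibble::tibble(
    gamma_hat = x$gamma_hat, gamma_se = x$gamma_se,
    slope_m = x$slope_m, slope_se = x$slope_se,
    e_modulus = x$e_modulus, n_obs = x$n_obs)
}

#' Tidy a Lorentzian peak fit
#'
#' @param x A `peak_fit` from [fit_lorentzian_peak()].
#' @param ... Unused.
#' @return One row per fitted parameter with `estimate`.
#' @method tidy peak_fit
#' @export
tidy.peak_fit <- function(x, ...) {
  tibble::tibble(
    term = c("q0", "fwhm", "amplitude", "b0", "b1"),
    estimate = c(x$q0, x$fwhm, x$amplitude, x$background[1], x$background[2]),
    unit = c("1/A", "1/A", "intensity", "intensity", "intensity*A"))
}

#' @rdname tidy.peak_fit
#' @method glance peak_fit
#' @export
glance.peak_fit <- function(x, ...) {
  tibble::tibble(
    q0 = x$q0, fwhm = x$fwhm, amplitude = x$amplitude,
    spacing_A = spacing_from_peak(x),
    xi_A = correlation_length_from_peak(x),
    residual_ss = x$residual_ss, n_points = x$n_points)
}
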