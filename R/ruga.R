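#' Forward buckle-delamination width model
#'
#' Width of a delamination buckle for an elastic film of thickness `t` under
#' compressive strain `eps` on a compliant substrate:
#' `lambda = t^{3/2} * pi * sqrt(2 * E_f * eps / Gamma)`,
#' the balance of bending, compression and film-substrate adhesion energy.
#' Computed internally in SI and returned in nm.
#'
#' @param t_nm Film thickness in nm (> 0). Vectorized.
#' @param strain Compressive strain as a fraction in `[0, 1)`. Vectorized.
#' @param e_modulus In-plane Young's modulus of the film, Pa (> 0).
#' @param gamma Film-substrate adhesion energy, J/m^2 (> 0).
#' @param poisson Optional Poisson ratio; when supplied the plane-strain
#'   modulus `E / (1 - nu^2)` is used instead of `E`, for sensitivity
#'   analysis. Default `NULL` uses `E` as given.
#' @return Buckle width lambda in nm. `strain = 0` gives 0.
#' @examples
#' buckle_width(100, 0.10, e_modulus = 42e6, gamma = 0.22)  # ~614 nm
#' @export
buckle_width <- function(t_nm, strain, e_modulus, gamma, poisson = NULL) {
  if (gamma <= 0 || e_modulus <= 0) {
    rlang::abort("gamma and e_modulus must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (any(t_nm <= 0)) {
    rlang::abort("thickness must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (any(strain < 0 | strain >= 1)) {
    rlang::abort("strain must lie in [0, 1)",
                 class = "lamellaflex_invalid_parameter")
  }
  e_eff <- if (is.null(poisson)) e_modulus else e_modulus / (1 - poisson^2)
  t_m <- t_nm * 1e-9
  lam_m <- t_m^1.5 * pi * sqrt(2 * e_eff * strain / gamma)
  lam_m * 1e9
}

#' Invert the buckle-width model for the adhesion energy
#'
#' Estimates the film-substrate adhesion energy Gamma from measured buckle
#' geometries by the exact linearization of the width model:
#' `lambda / t^{3/2} = m * sqrt(strain)` with slope `m = pi * sqrt(2 E / Gamma)`,
#' fit by unweighted through-origin least squares, so that
#' `Gamma_hat = 2 * pi^2 * E / m^2`. The standard error is first-order (delta
#' method) propagation from the slope standard error:
#' `se(Gamma) = 2 * Gamma_hat * se(m) / m`.
#'
#' Thicknesses outside the 70-150 nm validity band used for the reference
#' measurements trigger a warning, not an error.
#'
#' @param obs Data frame with columns `lambda_nm`, `t_nm`, `strain` (one row
#'   per measured buckle), e.g. from [simulate_buckles()] or [read_buckles()].
#' @param e_modulus In-plane Young's modulus of the film in Pa; default 42 MPa.
#' @param poisson Optional Poisson ratio (see [buckle_width()]).
#' @return An `adhesion_fit` object: list with `gamma_hat` and `gamma_se`
#'   (J/m^2), `slope_m` and `slope_se` (m^(-1/2)), `n_obs`, `e_modulus`, and
#'   the observations. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' obs <- simulate_buckles(rel_noise = 0, seed = 1)
#' fit_adhesion_energy(obs, e_modulus = 42e6)$gamma_hat  # 0.22
#' @export
fit_adhesion_energy <- function(obs, e_modulus = 42e6, poisson = NULL) {
  obs <- tibble::as_tibble(obs)
  required <- c("lambda_nm", "t_nm", "strain")
  if (!all(required %in% names(obs))) {
    rlang::abort("obs needs columns lambda_nm, t_nm, strain",
                 class = "lamellaflex_invalid_parameter")
  }
  if (nrow(obs) < 2) {
    rlang::abort("need at least two buckle observations",
                 class = "lamellaflex_underdetermined")
  }
  if (e_modulus <= 0) {
    rlang::abort("e_modulus must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (any(obs$lambda_nm <= 0) || any(obs$t_nm <= 0) ||
      any(obs$strain <= 0 | obs$strain >= 1)) {
    rlang::abort("observations must have lambda > 0, t > 0, 0 < strain < 1",
                 class = "lamellaflex_invalid_parameter")
  }
  if (any(obs$t_nm < 70 | obs$t_nm > 150)) {
    rlang::warn("thickness outside the 70-150 nm validity band")
  }
  e_eff <- if (is.null(poisson)) e_modulus else e_modulus / (1 - poisson^2)

  y <- (obs$lambda_nm * 1e-9) / (obs$t_nm * 1e-9)^1.5  # m^(-1/2)
  x <- sqrt(obs$strain)
  fit <- stats::lm(y ~ 0 + x)
  m <- unname(stats::coef(fit)[1])
  # slope SE of the through-origin regression, without summary.lm's
  # zero-residual warning on noise-free data
  m_se <- sqrt(sum(stats::residuals(fit)^2) / (nrow(obs) - 1) / sum(x^2))
  gamma_hat <- 2 * pi^2 * e_eff / m^2
  gamma_se <- 2 * gamma_hat * m_se / m

  structure(
    list(gamma_hat = gamma_hat, gamma_se = gamma_se,
         slope_m = m, slope_se = m_se,
         n_obs = nrow(obs), e_modulus = e_eff,
         observations = obs),
    class = "adhesion_fit")
}

#' @export
print.adhesion_fit <- function(x, ...) {
  cat(sprintf(
    "<adhesion_fit> Gamma = %.3g +/- %.2g J/m^2 (slope %.4g m^-1/2, n = %d, E = %.3g Pa)\n",
    x$gamma_hat, x$gamma_se, x$slope_m, x$n_obs, x$e_modulus))
  invisible(x)
}

#' Root-mean-square roughness of a topography map
#'
#' @param topo A `topography_map` (see [simulate_topography()]) or a plain
#'   numeric matrix of heights in nm.
#' @param detrend Detrending applied before the RMS: `"none"` (default;
#'   deviations from the mean height), `"plane"` (subtract the least-squares
#'   plane) or `"line"` (subtract a least-squares line from each fast-scan
#'   row, i.e. each y-row along x).
#' @return RMS of the residual heights, nm.
#' @examples
#' topo <- simulate_topography(256, 32, pixel_size = 10,
#'                             wrinkle_amplitude = 6.2225,
#'                             wrinkle_wavelength = 320)
#' rms_roughness(topo)  # ~4.4
#' @export
rms_roughness <- function(topo, detrend = c("none", "plane", "line")) {
  detrend <- match.arg(detrend)
  h <- if (inherits(topo, "topography_map")) topo$heights else as.matrix(topo)
  if (nrow(h) < 4 || ncol(h) < 4) {
    rlang::abort("need at least a 4 x 4 grid",
                 class = "lamellaflex_invalid_parameter")
  }
  r <- switch(detrend,
    none = h - mean(h),
    plane = {
      xs <- col(h); ys <- row(h)
      fit <- stats::lm.fit(cbind(1, as.vector(xs), as.vector(ys)),
                           as.vector(h))
      matrix(fit$residuals, nrow(h), ncol(h))
    },
    line = {
      xs <- seq_len(ncol(h))
      t(apply(h, 1, function(row) stats::lm.fit(cbind(1, xs), row)$residuals))
    })
  sqrt(mean(r^2))
}

#' Extract buckle widths and heights from a 1D topography profile
#'
#' Detects delamination buckles along a height profile. The baseline is a
#' running median (window five times the largest expected buckle width, or the
#' whole profile when no width is given). Pixels rising more than
#' `max(3 * robust SD, h_min)` above the baseline seed candidate regions,
#' where the robust SD is the median absolute deviation of the residual
#' scaled by 1.4826. Each candidate is then grown outward to the
#' baseline-crossing level, candidates separated by fewer than 3 pixels are
#' merged, and the width is the grown extent times the pixel size.
#'
#' @param profile Numeric vector of heights in nm (length >= 16).
#' @param pixel_size Pixel size in nm.
#' @param max_width Largest expected buckle width in nm; sets the running
#'   median window to `5 * max_width`. `NULL` (default) uses the global
#'   median of the profile as baseline.
#' @param h_min Minimum height above baseline to count as a buckle, nm
#'   (default 2).
#' @return A tibble with one row per detected buckle: `width_nm`, `height_nm`,
#'   `center_nm`. Zero rows when nothing rises above the threshold.
#' @examples
#' x <- (1:512 - 0.5) * 10
#' prof <- ifelse(abs(x - 2500) < 300,
#'                25 * (1 + cos(pi * (x - 2500) / 300)), 0)
#' extract_buckle_geometry(prof, pixel_size = 10)
#' @export
extract_buckle_geometry <- function(profile, pixel_size, max_width = NULL,
                                    h_min = 2) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 16) {
    rlang::abort("profile must have at least 16 samples",
                 class = "lamellaflex_invalid_parameter")
  }
  if (pixel_size <= 0) {
    rlang::abort("pixel_size must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  baseline <- if (is.null(max_width)) {
    rep(stats::median(profile), n)
  } else {
    win <- min(n, max(3, round(5 * max_width / pixel_size)))
    if (win %% 2 == 0) win <- win + 1
    stats::runmed(profile, k = win, endrule = "median")
  }
  resid <- profile - baseline
  thr <- max(3 * stats::mad(resid), h_min)
  above <- resid > thr
  if (!any(above)) {
    return(tibble::tibble(width_nm = numeric(0), height_nm = numeric(0),
                          center_nm = numeric(0)))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  regions <- cbind(starts[runs$values], ends[runs$values])
  # grow each region outward to the baseline-crossing level
  grown <- t(apply(regions, 1, function(r) {
    a <- r[1]; b <- r[2]
    while (a > 1 && resid[a - 1] > 0) a <- a - 1
    while (b < n && resid[b + 1] > 0) b <- b + 1
    c(a, b)
  }))
  grown <- grown[order(grown[, 1]), , drop = FALSE]
  # merge regions separated by < 3 pixels
  merged <- grown[1, , drop = FALSE]
  if (nrow(grown) > 1) {
    for (i in 2:nrow(grown)) {
      if (grown[i, 1] - merged[nrow(merged), 2] < 3) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], grown[i, 2])
        merged[nrow(merged), 1] <- min(merged[nrow(merged), 1], grown[i, 1])
      } else {
        merged <- rbind(merged, grown[i, , drop = FALSE])
      }
    }
  }
  tibble::tibble(
    width_nm = (merged[, 2] - merged[, 1] + 1) * pixel_size,
    height_nm = apply(merged, 1, function(r)
      max(profile[r[1]:r[2]] - baseline[r[1]:r[2]])),
    center_nm = (rowMeans(merged) - 0.5) * pixel_size
  )
}
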