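#' Simulate an undulated stacked lipid multilayer
#'
#' Generates a coarse-grained stack of `n_layers` bilayer leaflet surfaces with
#' a one-dimensional sinusoidal undulation along x. Layer `l` follows the
#' surface `z_l(x) = l * layer_spacing + amplitude * sin(2*pi*x/wavelength +
#' l * phase_per_layer)`. Each lipid is a rigid straight bead chain of length
#' `(beads_per_lipid - 1) * bond_length` laid along the local surface normal,
#' its head bead sitting on the surface at a point of a uniform x-y grid.
#' Orientational (director) noise is applied as a rotation of the whole chain
#' away from the surface normal by `|N(0, angular_noise_sd)|` degrees (folded
#' at 90) about a uniformly random azimuth.
#'
#' For a noise-free sinusoid the analytic tilt of a lipid at position x is
#' `atan(|A k cos(k x)|)` with `k = 2*pi/wavelength`; because the slope of a
#' sinusoid spends most of its time near its extremes, the modal tilt over a
#' uniform grid is `atan(A k)`.
#'
#' @param n_layers Number of stacked layers (>= 1).
#' @param lipids_per_layer Lipids per layer (>= 2).
#' @param amplitude Undulation amplitude in Angstrom (>= 0). The default,
#'   together with the default wavelength, gives a modal tilt near 10 degrees,
#'   typical of an uncompressed gel-phase multilayer.
#' @param wavelength Undulation wavelength in Angstrom (> 0).
#' @param phase_per_layer Phase offset between consecutive layers in radians;
#'   0 (default) gives in-phase undulations across the stack.
#' @param layer_spacing Inter-layer repeat distance d in Angstrom; default
#'   56 A (5.6 nm), the gel-phase DPPC lamellar repeat.
#' @param angular_noise_sd Standard deviation of the director-noise rotation
#'   in degrees (>= 0).
#' @param beads_per_lipid Beads per chain (>= 2); default 12.
#' @param bond_length Bond length in Angstrom; default 1.5.
#' @param pitch Lateral grid pitch in Angstrom; default 8 (about 0.64 nm^2
#'   per lipid).
#' @param seed Integer seed; identical seeds and parameters give bit-identical
#'   configurations.
#' @return A [lipid_configuration].
#' @examples
#' cfg <- simulate_multilayer(n_layers = 2, lipids_per_layer = 100,
#'                            amplitude = 0, angular_noise_sd = 0, seed = 1)
#' all(tilt_angles(compute_directors(cfg))$tilt_deg == 0)
#' @export
simulate_multilayer <- function(n_layers = 4, lipids_per_layer = 2500,
                                amplitude = 11.2, wavelength = 400,
                                phase_per_layer = 0, layer_spacing = 56,
                                angular_noise_sd = 0, beads_per_lipid = 12,
                                bond_length = 1.5, pitch = 8, seed = 1) {
  if (wavelength <= 0 || layer_spacing <= 0) {
    rlang::abort("wavelength and layer_spacing must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (amplitude < 0 || angular_noise_sd < 0) {
    rlang::abort("amplitude and angular_noise_sd must be >= 0",
                 class = "lamellaflex_invalid_parameter")
  }
  if (n_layers < 1 || lipids_per_layer < 2 || beads_per_lipid < 2) {
    rlang::abort(
      "need n_layers >= 1, lipids_per_layer >= 2, beads_per_lipid >= 2",
      class = "lamellaflex_invalid_parameter")
  }
  nx <- ceiling(sqrt(lipids_per_layer))
  ny <- ceiling(lipids_per_layer / nx)
  chain_len <- (beads_per_lipid - 1) * bond_length
  box <- c(nx * pitch, ny * pitch,
           n_layers * layer_spacing + chain_len + 2 * amplitude)
  if (chain_len > min(box[1], box[2])) {
    rlang::abort("lipid footprint exceeds the lateral box",
                 class = "lamellaflex_geometry_error")
  }

  set.seed(seed)
  k <- 2 * pi / wavelength
  idx <- seq_len(lipids_per_layer) - 1L
  gx <- (idx %% nx + 0.5) * pitch
  gy <- (idx %/% nx + 0.5) * pitch

  one_layer <- function(l) {
    phase <- l * phase_per_layer
    zs <- l * layer_spacing + amplitude * sin(k * gx + phase)
    slope <- amplitude * k * cos(k * gx + phase)
    # unit normal of z(x): (-z', 0, 1)/sqrt(1 + z'^2)
    nn <- sqrt(1 + slope^2)
    dir <- cbind(-slope / nn, 0, 1 / nn)
    if (angular_noise_sd > 0) {
      dir <- perturb_directions(dir, angular_noise_sd)
    }
    n <- length(gx)
    steps <- (seq_len(beads_per_lipid) - 1) * bond_length
    tibble::tibble(
      x = rep(gx, each = beads_per_lipid) +
        rep(dir[, 1], each = beads_per_lipid) * steps,
      y = rep(gy, each = beads_per_lipid) +
        rep(dir[, 2], each = beads_per_lipid) * steps,
      z = rep(zs, each = beads_per_lipid) +
        rep(dir[, 3], each = beads_per_lipid) * steps,
      lipid_id = rep(l * lipids_per_layer + seq_len(n), each = beads_per_lipid),
      layer_index = as.integer(l),
      bead_role = rep(
        c("head", rep("tail", max(0, beads_per_lipid - 2)), "terminal"), n)
    )
  }
  beads <- purrr::map_dfr(seq_len(n_layers) - 1L, one_layer)
  beads$z <- beads$z + amplitude  # keep everything above z = 0
  lipid_configuration(beads, box = box)
}

# Tilt each unit row-vector of `dir` by |N(0, sd_deg)| degrees (folded into
# [0, 90]) about a uniformly random azimuth in the plane perpendicular to it.
perturb_directions <- function(dir, sd_deg) {
  n <- nrow(dir)
  a <- abs(stats::rnorm(n, 0, sd_deg))
  a <- a %% 180
  a <- ifelse(a > 90, 180 - a, a) * pi / 180
  psi <- stats::runif(n, 0, 2 * pi)
  # orthonormal basis (u, v) perpendicular to each direction
  ref <- cbind(rep(1, n), 0, 0)
  swap <- abs(dir[, 1]) > 0.9
  if (any(swap)) {
    ref[swap, ] <- matrix(c(0, 1, 0), nrow = sum(swap), ncol = 3,
                          byrow = TRUE)
  }
  u <- cbind(ref[, 2] * dir[, 3] - ref[, 3] * dir[, 2],
             ref[, 3] * dir[, 1] - ref[, 1] * dir[, 3],
             ref[, 1] * dir[, 2] - ref[, 2] * dir[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(dir[, 2] * u[, 3] - dir[, 3] * u[, 2],
             dir[, 3] * u[, 1] - dir[, 1] * u[, 3],
             dir[, 1] * u[, 2] - dir[, 2] * u[, 1])
  cos(a) * dir + sin(a) * (cos(psi) * u + sin(psi) * v)
}

#' Simulate a one-dimensional scattering profile
#'
#' Builds an intensity-versus-q profile as a sum of Lorentzian peaks on a
#' linear background with additive Gaussian noise, emulating radially averaged
#' grazing-incidence scattering data. Intensities are clipped at zero.
#'
#' @param peaks Data frame with columns `q0` (peak centre, inverse Angstrom),
#'   `fwhm` (full width at half maximum, inverse Angstrom, > 0) and
#'   `amplitude` (peak height above background). May have zero rows.
#' @param q_grid Strictly increasing numeric vector of q values (1/Angstrom).
#' @param background Length-2 numeric `c(b0, b1)`: intensity `b0 + b1 * q`.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed.
#' @param label Free-text label stored on the profile.
#' @return A tibble with columns `q`, `intensity` and class
#'   `scattering_profile`.
#' @examples
#' prof <- simulate_scattering_profile(
#'   tibble::tibble(q0 = 1.514, fwhm = 0.061, amplitude = 100),
#'   q_grid = seq(1.2, 1.8, by = 0.002))
#' @export
simulate_scattering_profile <- function(peaks, q_grid,
                                        background = c(0, 0),
                                        noise_sd = 0, seed = 1,
                                        label = "synthetic") {
  if (any(diff(q_grid) <= 0)) {
    rlang::abort("q_grid must be strictly increasing",
                 class = "lamellaflex_invalid_parameter")
  }
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0) {
    if (any(peaks$fwhm <= 0)) {
      rlang::abort("all fwhm must be > 0",
                   class = "lamellaflex_invalid_parameter")
    }
    outside <- peaks$q0 < min(q_grid) | peaks$q0 > max(q_grid)
    if (any(outside)) {
      rlang::warn(paste0("peak centre(s) outside q_grid: ",
                         paste(signif(peaks$q0[outside], 5), collapse = ", ")))
    }
  }
  set.seed(seed)
  intensity <- background[1] + background[2] * q_grid
  if (nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      hw <- peaks$fwhm[i] / 2
      intensity <- intensity +
        peaks$amplitude[i] * hw^2 / ((q_grid - peaks$q0[i])^2 + hw^2)
    }
  }
  if (noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(q_grid), 0, noise_sd)
  }
  scattering_profile(q = q_grid, intensity = pmax(intensity, 0),
                     label = label)
}

#' @rdname simulate_scattering_profile
#' @param q,intensity Numeric vectors (see above) for direct construction.
#' @export
scattering_profile <- function(q, intensity, label = "") {
  if (length(q) != length(intensity) || length(q) < 8) {
    rlang::abort("need equal-length q and intensity with >= 8 points",
                 class = "lamellaflex_invalid_profile")
  }
  if (any(diff(q) <= 0)) {
    rlang::abort("q must be strictly increasing",
                 class = "lamellaflex_invalid_profile")
  }
  if (any(intensity < 0)) {
    rlang::abort("intensity must be nonnegative",
                 class = "lamellaflex_invalid_profile")
  }
  structure(tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity)),
            label = label,
            class = c("scattering_profile", class(tibble::tibble())))
}

#' Simulate a wrinkled / buckled topography map
#'
#' Builds a height map as a sinusoidal wrinkle field with ridges perpendicular
#' to x, plus raised-cosine delamination-buckle cross-sections, plus additive
#' Gaussian noise — emulating AFM topography of a compressed film.
#'
#' @param nx,ny Grid size in pixels.
#' @param pixel_size Physical pixel size in nm (> 0).
#' @param wrinkle_amplitude Wrinkle amplitude in nm.
#' @param wrinkle_wavelength Wrinkle wavelength in nm (> 0 when amplitude > 0).
#' @param buckles Data frame with columns `center` (nm along x), `width`
#'   (buckle width lambda, nm) and `height` (nm). Each contributes
#'   `height/2 * (1 + cos(2*pi*(x - center)/width))` for `|x - center| <
#'   width/2`, uniform along y. May have zero rows (default).
#' @param noise_sd Additive Gaussian height noise SD in nm.
#' @param seed Integer seed.
#' @return A `topography_map`: list with `heights` (ny x nx matrix, nm) and
#'   `pixel_size` (nm).
#' @examples
#' topo <- simulate_topography(128, 64, pixel_size = 10,
#'                             wrinkle_amplitude = 5, wrinkle_wavelength = 200)
#' rms_roughness(topo)
#' @export
simulate_topography <- function(nx, ny, pixel_size,
                                wrinkle_amplitude = 0,
                                wrinkle_wavelength = 100,
                                buckles = NULL, noise_sd = 0, seed = 1) {
  if (pixel_size <= 0) {
    rlang::abort("pixel_size must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (wrinkle_amplitude > 0 && wrinkle_wavelength <= 0) {
    rlang::abort("wrinkle_wavelength must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  set.seed(seed)
  xs <- (seq_len(nx) - 0.5) * pixel_size
  row_profile <- if (wrinkle_amplitude > 0) {
    wrinkle_amplitude * sin(2 * pi * xs / wrinkle_wavelength)
  } else {
    rep(0, nx)
  }
  if (!is.null(buckles) && nrow(buckles) > 0) {
    if (any(buckles$width <= 0)) {
      rlang::abort("buckle widths must be positive",
                   class = "lamellaflex_invalid_parameter")
    }
    if (any(buckles$width < 2 * pixel_size)) {
      rlang::abort("buckle width below two pixels is unresolvable",
                   class = "lamellaflex_invalid_parameter")
    }
    for (i in seq_len(nrow(buckles))) {
      u <- xs - buckles$center[i]
      inside <- abs(u) < buckles$width[i] / 2
      row_profile[inside] <- row_profile[inside] +
        buckles$height[i] / 2 * (1 + cos(2 * pi * u[inside] / buckles$width[i]))
    }
  }
  heights <- matrix(rep(row_profile, each = ny), nrow = ny, ncol = nx)
  if (noise_sd > 0) {
    heights <- heights + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
  }
  topography_map(heights, pixel_size)
}

#' @rdname simulate_topography
#' @param heights Numeric matrix of heights in nm for direct construction.
#' @export
topography_map <- function(heights, pixel_size) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) {
    rlang::abort("heights must be finite",
                 class = "lamellaflex_invalid_parameter")
  }
  if (pixel_size <= 0) {
    rlang::abort("pixel_size must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  structure(list(heights = heights, pixel_size = as.numeric(pixel_size)),
            class = "topography_map")
}

#' @export
print.topography_map <- function(x, ...) {
  cat(sprintf("<topography_map> %d x %d pixels, %.3g nm/pixel, height range [%.3g, %.3g] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @method as_tibble topography_map
#' @export
as_tibble.topography_map <- function(x, ...) {
  h <- x$heights
  tibble::tibble(
    x = rep((seq_len(ncol(h)) - 0.5) * x$pixel_size, each = nrow(h)),
    y = rep((seq_len(nrow(h)) - 0.5) * x$pixel_size, times = ncol(h)),
    height = as.vector(h)
  )
}

#' Simulate buckle-delamination observations from the mechanics model
#'
#' Draws `(lambda, t, strain)` triples from the buckle-delamination relation
#' `lambda = t^1.5 * pi * sqrt(2 * E * strain / gamma)`: film thickness `t`
#' uniform over `thickness_range`, strain cycled through `strains` in balanced
#' round-robin order, and multiplicative Gaussian noise `(1 + N(0, rel_noise))`
#' on the buckle width (redrawn if the width would be nonpositive).
#'
#' The defaults reproduce the reference study design: twelve buckles at
#' strains of 5, 10 and 14 %, thicknesses between 70 and 150 nm, film modulus
#' 42 MPa and adhesion energy 0.22 J/m^2.
#'
#' @param n Number of observations.
#' @param gamma Adhesion energy in J/m^2 (> 0).
#' @param e_modulus In-plane Young's modulus of the film in Pa (> 0).
#' @param thickness_range Length-2 range of film thickness in nm.
#' @param strains Vector of compressive strains, each in (0, 1).
#' @param rel_noise Relative (multiplicative) noise on lambda, < 1.
#' @param seed Integer seed.
#' @return A tibble with columns `lambda_nm`, `t_nm`, `strain`.
#' @examples
#' obs <- simulate_buckles(seed = 7)
#' fit_adhesion_energy(obs, e_modulus = 42e6)
#' @export
simulate_buckles <- function(n = 12, gamma = 0.22, e_modulus = 42e6,
                             thickness_range = c(70, 150),
                             strains = c(0.05, 0.10, 0.14),
                             rel_noise = 0.10, seed = 1) {
  if (gamma <= 0 || e_modulus <= 0) {
    rlang::abort("gamma and e_modulus must be positive",
                 class = "lamellaflex_invalid_parameter")
  }
  if (any(strains <= 0 | strains >= 1)) {
    rlang::abort("strains must lie strictly in (0, 1)",
                 class = "lamellaflex_invalid_parameter")
  }
  if (rel_noise >= 1 || rel_noise < 0) {
    rlang::abort("rel_noise must lie in [0, 1)",
                 class = "lamellaflex_invalid_parameter")
  }
  set.seed(seed)
  t_nm <- stats::runif(n, thickness_range[1], thickness_range[2])
  strain <- rep_len(strains, n)
  lam0 <- buckle_width(t_nm, strain,
                       e_modulus = e_modulus, gamma = gamma)
  lam <- lam0
  if (rel_noise > 0) {
    fac <- 1 + stats::rnorm(n, 0, rel_noise)
    while (any(fac <= 0)) {
      redo <- fac <= 0
      fac[redo] <- 1 + stats::rnorm(sum(redo), 0, rel_noise)
    }
    lam <- lam0 * fac
  }
  tibble::tibble(lambda_nm = lam, t_nm = t_nm, strain = strain)
}
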