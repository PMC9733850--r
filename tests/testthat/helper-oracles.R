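# Independent oracles used across the test files.

# Brute-force Lorentzian fit: grid over (q0, fwhm) with the linear parameters
# (amplitude, b0, b1) solved analytically at each grid point. Returns the best
# sum of squares and its arguments. Independent of the package's optimizer.
grid_lorentzian_fit <- function(q, intensity, q0_grid, fwhm_grid) {
  best <- list(ss = Inf, q0 = NA, fwhm = NA)
  for (q0 in q0_grid) {
    dq <- q - q0
    for (fw in fwhm_grid) {
      hw <- fw / 2
      shape <- hw^2 / (dq^2 + hw^2)
      X <- cbind(shape, 1, dq)
      fit <- stats::lm.fit(X, intensity)
      ss <- sum(fit$residuals^2)
      if (ss < best$ss) best <- list(ss = ss, q0 = q0, fwhm = fw)
    }
  }
  best
}

# Analytic membrane-normal P2 of rigid chains riding a sinusoid of amplitude
# A and wavelength L: quadrature of (3 cos^2(theta(x)) - 1)/2 over one period,
# with cos(theta) = 1/sqrt(1 + z'(x)^2).
p2_sinusoid_quadrature <- function(amplitude, wavelength) {
  k <- 2 * pi / wavelength
  f <- function(x) {
    c2 <- 1 / (1 + (amplitude * k * cos(k * x))^2)
    (3 * c2 - 1) / 2
  }
  stats::integrate(f, 0, wavelength, rel.tol = 1e-10)$value / wavelength
}

# Uniform random unit vectors (n x 3).
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Rotate a configuration rigidly about the z axis by `deg` degrees.
rotate_config_z <- function(config, deg) {
  th <- deg * pi / 180
  x <- config$x * cos(th) - config$y * sin(th)
  y <- config$x * sin(th) + config$y * cos(th)
  beads <- tibble::as_tibble(config)
  shift <- function(v) v - min(v) + 1
  beads$x <- shift(x)
  beads$y <- shift(y)
  box <- attr(config, "box")
  lipid_configuration(beads, box = c(max(beads$x) + 1, max(beads$y) + 1,
                                     box[3]))
}
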