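test_that("all generators are deterministic under a fixed seed", {
  a <- simulate_multilayer(2, 50, angular_noise_sd = 5, seed = 11)
  b <- simulate_multilayer(2, 50, angular_noise_sd = 5, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))

  peaks <- tibble::tibble(q0 = 0.5, fwhm = 0.02, amplitude = 10)
  q <- seq(0.2, 0.8, by = 0.002)
  expect_identical(
    simulate_scattering_profile(peaks, q, noise_sd = 1, seed = 4)$intensity,
    simulate_scattering_profile(peaks, q, noise_sd = 1, seed = 4)$intensity)

  expect_identical(
    simulate_topography(64, 32, 10, 3, 200, noise_sd = 0.5, seed = 9)$heights,
    simulate_topography(64, 32, 10, 3, 200, noise_sd = 0.5, seed = 9)$heights)

  expect_identical(simulate_buckles(seed = 2), simulate_buckles(seed = 2))
})

test_that("flat noise-free multilayer has all lipids parallel to z", {
  cfg <- simulate_multilayer(3, 100, amplitude = 0, angular_noise_sd = 0,
                             seed = 1)
  tilts <- tilt_angles(compute_directors(cfg))$tilt_deg
  expect_equal(tilts, rep(0, 300))
  expect_equal(order_parameter_p2(cfg)$p2, 1)
})

test_that("undulation slope sets the modal tilt at arctan(A k)", {
  # slope amplitude tan(22.5 deg): the analytic mode of the tilt distribution
  A <- tan(22.5 * pi / 180) * 400 / (2 * pi)
  cfg <- simulate_multilayer(2, 2500, amplitude = A, wavelength = 400,
                             angular_noise_sd = 0, seed = 1)
  h <- tilt_histogram(tilt_angles(compute_directors(cfg)), bin_width = 1)
  expect_lt(abs(modal_tilt(h) - 22.5), 1)
})

test_that("director-renormalized bond order is exactly 1 for rigid chains", {
  for (A in c(0, 10, 30)) {
    cfg <- simulate_multilayer(2, 64, amplitude = A, wavelength = 200,
                               angular_noise_sd = 8, seed = 5)
    expect_equal(order_parameter_p2(cfg, "lipid_director")$p2, 1,
                 tolerance = 1e-12)
  }
})

test_that("multilayer generator rejects invalid geometry and parameters", {
  expect_error(simulate_multilayer(2, 50, wavelength = -1),
               class = "lamellaflex_invalid_parameter")
  expect_error(simulate_multilayer(2, 50, layer_spacing = 0),
               class = "lamellaflex_invalid_parameter")
  expect_error(simulate_multilayer(1, 4, beads_per_lipid = 30,
                                   bond_length = 10, pitch = 4),
               class = "lamellaflex_geometry_error")
})

test_that("scattering generator reproduces its construction", {
  q <- seq(1.2, 1.8, by = 0.001)
  prof <- simulate_scattering_profile(
    tibble::tibble(q0 = 1.514, fwhm = 0.06, amplitude = 50), q, noise_sd = 0)
  expect_equal(prof$q[which.max(prof$intensity)], q[which.min(abs(q - 1.514))])

  # two lamellar orders produce two local maxima at the harmonic positions
  q2 <- seq(0.05, 0.35, by = 5e-4)
  prof2 <- simulate_scattering_profile(
    tibble::tibble(q0 = c(0.1122, 0.2244), fwhm = 0.004,
                   amplitude = c(100, 40)), q2)
  i <- prof2$intensity
  local_max <- which(diff(sign(diff(i))) == -2) + 1
  peaks_q <- prof2$q[local_max[order(i[local_max], decreasing = TRUE)][1:2]]
  expect_equal(sort(peaks_q), c(0.1122, 0.2244), tolerance = 1e-3)

  flat <- simulate_scattering_profile(
    tibble::tibble(q0 = numeric(0), fwhm = numeric(0), amplitude = numeric(0)),
    q, background = c(5, 0))
  expect_equal(flat$intensity, rep(5, length(q)))

  expect_warning(simulate_scattering_profile(
    tibble::tibble(q0 = 5, fwhm = 0.1, amplitude = 1), q), "outside")
  expect_error(simulate_scattering_profile(
    tibble::tibble(q0 = 1.5, fwhm = 0, amplitude = 1), q),
    class = "lamellaflex_invalid_parameter")
  expect_error(simulate_scattering_profile(
    tibble::tibble(q0 = 1.5, fwhm = 0.1, amplitude = 1), rev(q)),
    class = "lamellaflex_invalid_parameter")
})

test_that("topography generator matches its closed forms", {
  flat <- simulate_topography(64, 64, 10)
  expect_equal(rms_roughness(flat), 0)

  # pure sinusoid: RMS = A / sqrt(2) over whole periods
  topo <- simulate_topography(512, 32, 10, wrinkle_amplitude = 6.2225,
                              wrinkle_wavelength = 640)
  expect_equal(rms_roughness(topo), 6.2225 / sqrt(2), tolerance = 0.01)

  # one raised-cosine buckle recovered at its constructed width
  topo2 <- simulate_topography(
    512, 16, 10, buckles = tibble::tibble(center = 2500, width = 600,
                                          height = 50))
  geom <- extract_buckle_geometry(topo2$heights[1, ], pixel_size = 10)
  expect_equal(nrow(geom), 1)
  expect_lt(abs(geom$width_nm - 600), 2 * 10 + 1e-9)
  expect_equal(geom$height_nm, 50, tolerance = 0.01)

  expect_error(simulate_topography(
    64, 64, 10, buckles = tibble::tibble(center = 100, width = 15,
                                         height = 5)),
    class = "lamellaflex_invalid_parameter")
  expect_error(simulate_topography(64, 64, 0),
               class = "lamellaflex_invalid_parameter")
})

test_that("buckle datasets follow the forward model", {
  obs <- simulate_buckles(n = 20, rel_noise = 0, seed = 8)
  expect_equal(obs$lambda_nm,
               buckle_width(obs$t_nm, obs$strain, 42e6, 0.22),
               tolerance = 1e-12)
  # balanced strain design: 12 observations cycle 3 strains 4 times
  obs12 <- simulate_buckles(n = 12, seed = 1)
  expect_equal(as.integer(table(obs12$strain)), c(4L, 4L, 4L))
  expect_true(all(obs12$lambda_nm > 0))
  expect_true(all(obs12$t_nm >= 70 & obs12$t_nm <= 150))
  expect_error(simulate_buckles(rel_noise = 1),
               class = "lamellaflex_invalid_parameter")
  expect_error(simulate_buckles(strains = c(0.5, 1.2)),
               class = "lamellaflex_invalid_parameter")
})
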