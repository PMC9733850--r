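test_that("directors follow the head-to-terminal axis, folded to z >= 0", {
  up <- chains_from_directors(rbind(c(0, 0, 1)), beads_per_lipid = 3,
                              bond_length = 10)
  d <- compute_directors(up)
  expect_equal(c(d$dx, d$dy, d$dz), c(0, 0, 1))
  expect_equal(d$tilt_deg, 0)

  side <- chains_from_directors(rbind(c(1, 0, 0)), beads_per_lipid = 3,
                                bond_length = 10)
  ds <- compute_directors(side)
  expect_equal(c(ds$dx, ds$dy, ds$dz), c(1, 0, 0))
  expect_equal(ds$tilt_deg, 90)

  # downward-pointing chains fold into the upper hemisphere
  down <- chains_from_directors(rbind(c(0.5, 0, -1)))
  dd <- compute_directors(down)
  expect_gte(dd$dz, 0)

  degen <- tibble::tibble(
    x = c(0, 0), y = 0, z = c(5, 5), lipid_id = 1L, layer_index = 0L,
    bead_role = c("head", "terminal"))
  expect_error(compute_directors(lipid_configuration(degen, c(10, 10, 10))),
               class = "lamellaflex_degenerate_lipid")
})

test_that("noise-free undulation directors equal the analytic surface normals", {
  A <- 15; L <- 200
  cfg <- simulate_multilayer(2, 625, amplitude = A, wavelength = L,
                             angular_noise_sd = 0, seed = 1)
  d <- compute_directors(cfg)
  k <- 2 * pi / L
  slope <- A * k * cos(k * d$x)  # head x-positions sit on the surface grid
  nn <- sqrt(1 + slope^2)
  expect_equal(d$dx, -slope / nn, tolerance = 1e-9)
  expect_equal(d$dz, 1 / nn, tolerance = 1e-9)

  # principal-axis directors agree for rigid straight chains
  dp <- compute_directors(cfg, method = "principal_axis")
  dp <- dp[order(dp$lipid_id), ]
  expect_equal(dp$dx, d$dx, tolerance = 1e-6)
  expect_equal(dp$dz, d$dz, tolerance = 1e-6)
})

test_that("tilt angles and histogram behave on constructed inputs", {
  th <- 22.5 * pi / 180
  dirs <- rbind(c(0, 0, 1), c(sin(th), 0, cos(th)), c(1, 0, 0))
  t <- tilt_angles(dirs)
  expect_equal(t$tilt_deg, c(0, 22.5, 90), tolerance = 1e-9)

  h0 <- tilt_histogram(rep(0, 10))
  expect_equal(modal_tilt(h0), 0.5)  # first bin centre
  expect_equal(sum(h0$count), 10)

  # ties break toward the smaller angle
  htie <- tilt_histogram(c(10.2, 10.4, 20.2, 20.4), bin_width = 1)
  expect_equal(modal_tilt(htie), 10.5)

  # uniform angles fill bins evenly (binomial sampling bound)
  set.seed(1)
  hu <- tilt_histogram(runif(1e6, 0, 90), bin_width = 1)
  expect_lt(max(hu$count) / min(hu$count), 1.1)

  expect_error(tilt_histogram(numeric(0)),
               class = "lamellaflex_invalid_parameter")
  expect_error(tilt_histogram(c(1, 2), bin_width = 0),
               class = "lamellaflex_invalid_parameter")
})

test_that("P2 hits its analytic limits and bounds", {
  up <- chains_from_directors(matrix(rep(c(0, 0, 1), 20), ncol = 3,
                                     byrow = TRUE))
  expect_equal(order_parameter_p2(up)$p2, 1)
  flat <- chains_from_directors(cbind(cos(1:20), sin(1:20), 0))
  expect_equal(order_parameter_p2(flat)$p2, -0.5)

  set.seed(9)
  iso <- chains_from_directors(random_unit_vectors(1e4))
  p2 <- order_parameter_p2(iso)$p2
  expect_lt(abs(p2), 3 / sqrt(1e4))

  # bounds hold on arbitrary random configurations
  for (s in 1:5) {
    set.seed(s)
    cfg <- chains_from_directors(random_unit_vectors(50),
                                 beads_per_lipid = sample(2:6, 1))
    p <- order_parameter_p2(cfg, include_head_bond = TRUE)$p2
    expect_gte(p, -0.5); expect_lte(p, 1)
  }
})

test_that("membrane-normal P2 of an undulated stack matches quadrature", {
  for (A in c(5, 15, 30)) {
    cfg <- simulate_multilayer(2, 2500, amplitude = A, wavelength = 400,
                               angular_noise_sd = 0, seed = 1)
    expect_equal(order_parameter_p2(cfg)$p2,
                 p2_sinusoid_quadrature(A, 400), tolerance = 1e-3)
  }
  # disorder grows with undulation amplitude
  p2s <- vapply(c(0, 10, 20, 30), function(A) {
    order_parameter_p2(simulate_multilayer(1, 900, amplitude = A,
                                           wavelength = 400, seed = 1))$p2
  }, numeric(1))
  expect_true(all(diff(p2s) < 0))
})

test_that("head bond exclusion flag changes the bond set", {
  # head bond bent away from the tail: excluding it leaves perfect order
  beads <- tibble::tibble(
    x = c(0, 5, 5, 5), y = 0, z = c(0, 0, 10, 20),
    lipid_id = 1L, layer_index = 0L,
    bead_role = c("head", "tail", "tail", "terminal"))
  cfg <- lipid_configuration(beads, box = c(50, 50, 50))
  expect_equal(order_parameter_p2(cfg)$p2, 1)
  expect_equal(order_parameter_p2(cfg)$n_bonds, 2)
  with_head <- order_parameter_p2(cfg, include_head_bond = TRUE)
  expect_equal(with_head$n_bonds, 3)
  expect_lt(with_head$p2, 1)
})

test_that("all order statistics are invariant under rotation about z", {
  cfg <- simulate_multilayer(2, 400, amplitude = 20, wavelength = 160,
                             angular_noise_sd = 5, seed = 12)
  rot <- rotate_config_z(cfg, 35)
  expect_equal(order_parameter_p2(rot)$p2, order_parameter_p2(cfg)$p2,
               tolerance = 1e-9)
  expect_equal(order_parameter_p2(rot, "lipid_director")$p2,
               order_parameter_p2(cfg, "lipid_director")$p2,
               tolerance = 1e-9)
  expect_equal(sort(tilt_angles(compute_directors(rot))$tilt_deg),
               sort(tilt_angles(compute_directors(cfg))$tilt_deg),
               tolerance = 1e-9)
})

test_that("a layer is perfectly correlated with its duplicate", {
  cfg <- simulate_multilayer(2, 900, amplitude = 25, wavelength = 120,
                             angular_noise_sd = 0, phase_per_layer = 0,
                             seed = 4)
  d <- compute_directors(cfg)
  corr <- interlayer_tilt_correlation(d, 0, 1, segments = 15)
  expect_equal(corr$correlation, 1, tolerance = 1e-6)
})

test_that("independent layers approach the analytic decorrelated ratio", {
  # one lipid per segment: the defining ratio reduces to
  # mean(theta_1 * theta_2) / mean(theta_1^2) ~= mean(theta)^2 / mean(theta^2)
  cfg <- simulate_multilayer(2, 2500, amplitude = 0,
                             angular_noise_sd = 10, seed = 21)
  d <- compute_directors(cfg)
  corr <- interlayer_tilt_correlation(d, 0, 1, segments = 50)$correlation
  t1 <- d$tilt_deg[d$layer_index == 0]
  t2 <- d$tilt_deg[d$layer_index == 1]
  oracle <- mean(t1 * t2) / mean(t1^2)  # Monte-Carlo of the defining ratio
  expect_equal(corr, oracle, tolerance = 1e-9)
  expect_equal(corr, mean(t1)^2 / mean(t1^2), tolerance = 0.05)
  expect_lt(corr, 1)
})

test_that("inter-layer correlation rises with undulation amplitude", {
  corr_at <- function(A) {
    cfg <- simulate_multilayer(2, 900, amplitude = A, wavelength = 120,
                               angular_noise_sd = 6, seed = 31)
    d <- compute_directors(cfg)
    interlayer_tilt_correlation(d, 0, 1, segments = 15)$correlation
  }
  cs <- vapply(c(0, 4, 10), corr_at, numeric(1))
  expect_true(all(diff(cs) > 0))
})

test_that("correlation input errors are classified", {
  cfg <- simulate_multilayer(1, 100, amplitude = 0, seed = 1)
  d <- compute_directors(cfg)
  expect_error(interlayer_tilt_correlation(d, 0, 1, segments = 5),
               class = "lamellaflex_invalid_parameter")
  # all-zero reference tilts are an undefined correlation
  cfg2 <- simulate_multilayer(2, 100, amplitude = 0, angular_noise_sd = 0,
                              seed = 1)
  d2 <- compute_directors(cfg2)
  expect_error(interlayer_tilt_correlation(d2, 0, 1, segments = 5),
               class = "lamellaflex_undefined_correlation")
  # pearson variant works on segment means
  cfg3 <- simulate_multilayer(2, 400, amplitude = 20, wavelength = 100,
                              angular_noise_sd = 3, seed = 2)
  d3 <- compute_directors(cfg3)
  pc <- interlayer_tilt_correlation(d3, 0, 1, segments = 10,
                                    method = "pearson")
  expect_true(pc$correlation > 0 && pc$correlation <= 1)
})
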