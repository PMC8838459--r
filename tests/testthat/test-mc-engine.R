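# Monte Carlo transport primitives and the voxel kernel.

test_that("step sampling follows the exponential attenuation law", {
  expect_equal(sample_step(1, 0.5, 0.5), 0)
  expect_equal(sample_step(exp(-1), 0.4, 0.6), 1)
  expect_identical(sample_step(0.5, 0, 0), Inf)
  set.seed(1)
  xi <- runif(1e6)
  s <- sample_step(1 - xi, 0.8, 1.2)  # mu_t = 2, mean 0.5
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.5), 3 * se)
  expect_error(sample_step(0, 1, 1), "\\(0, 1\\]")
})

test_that("Henyey-Greenstein sampling has first moment g", {
  expect_equal(sample_scatter_cos(0.25, 0), 0.5)
  expect_equal(sample_scatter_cos(0.5, 0.5), 0.6875)
  set.seed(2)
  for (g in c(0, 0.8, 0.95)) {
    ct <- sample_scatter_cos(runif(1e6), g)
    expect_true(all(ct >= -1 & ct <= 1))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
  expect_error(sample_scatter_cos(0.5, 1), "\\|g\\| < 1")
})

test_that("direction spin preserves norm and the polar angle", {
  d <- c(0, 0, 1)
  expect_equal(spin_direction(d, 1, 1.3), d)
  expect_equal(spin_direction(d, -1, 0.4), -d, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    ct <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
    out <- spin_direction(v, ct, phi)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
    expect_equal(sum(out * v), ct, tolerance = 1e-9)
  }
  expect_error(spin_direction(c(1, 1, 0), 0.5, 0), "unit")
})

test_that("Fresnel interaction reproduces closed-form reflectances", {
  same <- fresnel_interaction(1.4, 1.4, c(0, 0, 1), c(0, 0, 1), 0.99)
  expect_identical(same$action, "transmit")
  expect_equal(same$reflectance, 0)
  expect_equal(same$direction, c(0, 0, 1))
  # normal incidence air -> glass: R = ((n1-n2)/(n1+n2))^2 = 0.04
  ni <- fresnel_interaction(1, 1.5, c(0, 0, 1), c(0, 0, 1), 0.5)
  expect_equal(ni$reflectance, 0.04)
  expect_identical(ni$action, "transmit")
  # total internal reflection beyond the critical angle
  sin_i <- 0.9  # critical sin = 1/1.5 = 0.667
  d <- c(sin_i, 0, sqrt(1 - sin_i^2))
  tir <- fresnel_interaction(1.5, 1.0, d, c(0, 0, 1), 0.999999)
  expect_identical(tir$action, "reflect")
  expect_equal(tir$reflectance, 1)
  expect_equal(tir$direction, c(sin_i, 0, -sqrt(1 - sin_i^2)),
               tolerance = 1e-12)
  # Snell refraction preserves the tangential scaled component
  tr <- fresnel_interaction(1, 1.5, d, c(0, 0, 1), 0.999999)
  expect_identical(tr$action, "transmit")
  expect_equal(tr$direction[1], sin_i / 1.5, tolerance = 1e-12)
  expect_equal(sum(tr$direction^2), 1, tolerance = 1e-12)
})

test_that("ballistic transmittance matches the attenuation closed form", {
  lay <- data.frame(layer = "slab", thickness = 1, mu_a = 0.5, mu_s = 0,
                    g = 0, n = 1)
  g <- slab_grid(lay, pitch = 0.1, lateral = 20)
  r <- run_simulation(g, n_photons = 1e5, seed = 7, fluence = FALSE)
  expect_lt(abs(r$transmitted - exp(-0.5)), 3 * r$transmitted_se)
  expect_equal(r$reflected, 0)
  expect_equal(r$lateral, 0)
})

test_that("matched lossless medium returns every packet intact", {
  lay <- data.frame(layer = "void", thickness = 1, mu_a = 0, mu_s = 0,
                    g = 0, n = 1)
  g <- slab_grid(lay, pitch = 0.25, lateral = 10)
  r <- run_simulation(g, n_photons = 1000, seed = 1, fluence = FALSE)
  expect_equal(r$transmitted, 1)
  expect_equal(r$absorbed, 0)
})

test_that("global weight conservation holds on scattering media", {
  lay <- data.frame(layer = c("a", "b"), thickness = c(1, 1),
                    mu_a = c(0.05, 0.1), mu_s = c(2, 1), g = c(0.7, 0),
                    n = c(1.4, 1.37))
  g <- slab_grid(lay, pitch = 0.25, lateral = 60)
  r <- run_simulation(g, n_photons = 2e4, seed = 3, fluence = FALSE)
  expect_lt(r$conservation_error, 1e-9)
  expect_equal(r$capped_fraction, 0)
  # totals are sensible probabilities
  expect_true(all(c(r$reflected, r$transmitted, r$absorbed, r$lateral) >= 0))
  expect_lt(r$reflected + r$transmitted + r$absorbed + r$lateral - 1, 1e-9)
})

test_that("simulation is seed-deterministic and photon-count consistent", {
  g <- build_voxel_model(finger_geometry(voxel_pitch = 0.05,
                                         lateral_extent = 4),
                         pressure = 100, wavelength_nm = 940)
  r1 <- run_simulation(g, n_photons = 3000, seed = 42, fluence = FALSE)
  r2 <- run_simulation(g, n_photons = 3000, seed = 42, fluence = FALSE)
  expect_identical(r1$reflected, r2$reflected)
  expect_identical(r1$detected, r2$detected)
  r3 <- run_simulation(g, n_photons = 3000, seed = 43, fluence = FALSE)
  expect_false(identical(r1$reflected, r3$reflected))
  # doubling the photon budget agrees within 3 combined standard errors
  r4 <- run_simulation(g, n_photons = 6000, seed = 44, fluence = FALSE)
  se <- sqrt(r1$reflected_se^2 + r4$reflected_se^2)
  expect_lt(abs(r1$reflected - r4$reflected), 3 * se + 1e-12)
})

test_that("voxel engine agrees with the independent layered oracle", {
  lay <- data.frame(layer = c("a", "b"), thickness = c(1, 1),
                    mu_a = c(0.05, 0.1), mu_s = c(2, 1), g = c(0.7, 0),
                    n = c(1, 1))
  g <- slab_grid(lay, pitch = 0.25, lateral = 80)
  rv <- run_simulation(g, n_photons = 3e4, seed = 5, fluence = FALSE)
  ro <- layered_mc_oracle(lay, n_photons = 3e4, seed = 6)
  expect_lt(abs(rv$reflected - ro$R),
            3 * sqrt(rv$reflected_se^2 + ro$se_R^2))
  expect_lt(abs(rv$transmitted - ro$T),
            3 * sqrt(rv$transmitted_se^2 + ro$se_T^2))
})

test_that("detectors bin exit weights by face and aperture", {
  lay <- data.frame(layer = "slab", thickness = 0.5, mu_a = 0.01,
                    mu_s = 1, g = 0.5, n = 1)
  geom <- finger_geometry(voxel_pitch = 0.1, lateral_extent = 10,
                          layer_stack = lay, symmetric = FALSE,
                          artery = FALSE)
  g <- build_voxel_model(geom, wavelength_nm = 940)
  dets <- list(detector_spec("transmission", aperture = 1),
               detector_spec("transmission", aperture = 8),
               detector_spec("reflection"))
  r <- run_simulation(g, detectors = dets, n_photons = 5000, seed = 9,
                      fluence = FALSE)
  expect_lte(r$detected[1], r$detected[2])       # nested apertures
  expect_lte(r$detected[2], r$transmitted + 1e-12)
  expect_lte(r$detected[3], r$reflected + 1e-12)
  expect_error(detector_spec("transmission", aperture = 0), "positive")
})
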