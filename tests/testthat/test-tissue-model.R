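# Optical-property formulas, artery model and voxel geometry.

test_that("absorption power laws match independent evaluation and decrease in wavelength", {
  # frozen values from direct high-precision evaluation of the power laws
  expect_equal(baseline_absorption(905), 0.0186390999577, tolerance = 1e-10)
  expect_equal(baseline_absorption(940), 0.0164734627883, tolerance = 1e-10)
  expect_equal(melanin_absorption(905), 11.5505755254, tolerance = 1e-10)
  expect_equal(melanin_absorption(940), 10.1911224227, tolerance = 1e-10)
  expect_gt(baseline_absorption(905), baseline_absorption(940))
  lam <- seq(500, 1100, by = 50)
  expect_true(all(diff(melanin_absorption(lam)) < 0))
  expect_error(baseline_absorption(-1), "positive")
  expect_error(melanin_absorption(0), "positive")
})

test_that("epidermis absorption is the stated melanin/water mixture", {
  expect_equal(epidermis_absorption(905, 0, 0, mu_a_water = 0.008),
               baseline_absorption(905))
  expect_equal(epidermis_absorption(905, 1, 0, mu_a_water = 0.008),
               melanin_absorption(905))
  # independent convex-combination arithmetic
  muw <- 0.008
  expect_equal(
    epidermis_absorption(905, 0.10, 0.20, mu_a_water = muw),
    0.10 * melanin_absorption(905) + 0.20 * muw +
      0.70 * baseline_absorption(905))
  expect_error(epidermis_absorption(905, 0.7, 0.5), "sum")
})

test_that("stratum corneum absorption matches the arithmetic oracle", {
  muw <- 0.008
  expect_equal(stratum_corneum_absorption(905, 1, mu_a_water = muw), muw)
  # frozen: (0.1 - 0.3e-4*905) + 0.125 * baseline(905)
  expect_equal(stratum_corneum_absorption(905, 0, mu_a_water = muw),
               0.0751798874947, tolerance = 1e-10)
  expect_equal(
    stratum_corneum_absorption(905, 0.05, mu_a_water = muw),
    0.95 * 0.0751798874947 + 0.05 * muw, tolerance = 1e-9)
  expect_error(stratum_corneum_absorption(905, 1.2), "0, 1")
})

test_that("composite absorption equals the brute-force weighted sum", {
  expect_equal(composite_absorption(2.5, 1, 0.1), 2.5)
  expect_equal(composite_absorption(c(1, 2), c(0, 0), 0.3), 0.3)
  mus <- c(0.8, 1.7); vs <- c(0.3, 0.2); mu0 <- 0.05
  brute <- sum(vapply(1:2, function(i) mus[i] * vs[i], 1)) +
    mu0 * (1 - sum(vs))
  expect_equal(composite_absorption(mus, vs, mu0), brute)
  expect_error(composite_absorption(c(1, 2), 0.5, 0.1), "equal length")
})

test_that("artery diameter follows the dilation law and is increasing", {
  expect_equal(artery_diameter(1), 0.8531)
  expect_equal(artery_diameter(100), 1.36646949811, tolerance = 1e-10)
  expect_gt(artery_diameter(200), artery_diameter(42))
  p <- seq(42, 200, by = 1)
  expect_true(all(diff(artery_diameter(p)) > 0))
  expect_error(artery_diameter(0), "positive")
})

test_that("artery volume fractions follow the coaxial-cylinder geometry", {
  expect_equal(artery_volume_fractions(1, 0)$v_blood, 1)
  expect_equal(artery_volume_fractions(1, 0)$v_vw, 0)
  expect_gt(artery_volume_fractions(1000, 0.2)$v_blood, 0.999)
  vf <- artery_volume_fractions(1.36646949811, 0.2)
  expect_equal(vf$v_blood, 0.598394507074, tolerance = 1e-9)
  expect_equal(vf$v_blood + vf$v_vw, 1)
  # v_blood strictly increasing in diameter at fixed wall
  d <- seq(0.5, 2, by = 0.1)
  vb <- vapply(d, function(x) artery_volume_fractions(x, 0.2)$v_blood, 1)
  expect_true(all(diff(vb) > 0))
})

test_that("artery absorption mixes packaged whole-blood and wall coefficients", {
  expect_equal(artery_absorption(905, 1, 0), 0.011160)
  expect_equal(artery_absorption(940, 0, 1), 0.009316)
  expect_equal(artery_absorption(940, 0.5985, 0.4015),
               0.5985 * 0.011778 + 0.4015 * 0.009316)
  expect_error(artery_absorption(808, 0.5, 0.5), "supply")
  expect_equal(artery_absorption(808, 0.5, 0.5,
                                 mu_blood = 0.02, mu_vw = 0.01), 0.015)
  expect_error(artery_absorption(905, 0.6, 0.6), "equal 1")
})

test_that("packaged layer properties match the printed constants exactly", {
  p905 <- finger_layer_properties(905)
  p940 <- finger_layer_properties(940)
  expect_identical(p905$layer[1], "stratum_corneum")
  expect_identical(p905$mu_a,
                   c(0.11350, 0.16825, 0.09631, 0.09864, 0.09824, 0.10118,
                     0.0142, 0.031, 0.15))
  expect_identical(p940$mu_a,
                   c(0.09745, 0.21397, 0.23308, 0.24202, 0.29906, 0.32549,
                     0.0170, 0.0401, 0.0457))
  expect_identical(p905$mu_s,
                   c(100, 45, 30, 35, 25, 30, 6.33, 1.83, 15.2))
  expect_identical(p940$mu_s,
                   c(100, 45, 30, 35, 25, 30, 5.42, 5.81, 24.70))
  expect_identical(p905$g,
                   c(0.86, 0.8, 0.9, 0.95, 0.8, 0.95, 0.8, 0.5, 0.92))
  expect_identical(p905$n,
                   c(1.5, 1.34, 1.4, 1.39, 1.4, 1.38, 1.37, 1.37, 1.37))
  expect_identical(p905$thickness,
                   c(0.02, 0.25, 0.1, 0.08, 0.2, 0.3, 0.55, 1.5, 2))
  expect_identical(p905$g, p940$g)
  ov <- finger_layer_properties(940, list(epidermis = list(mu_a = 0.5)))
  expect_equal(ov$mu_a[ov$layer == "epidermis"], 0.5)
  expect_error(finger_layer_properties(800), "905 and 940")
})

test_that("voxel model realizes the layer stack, artery and determinism", {
  geom <- finger_geometry(voxel_pitch = 0.05, lateral_extent = 4)
  g100 <- build_voxel_model(geom, pressure = 100, wavelength_nm = 940)
  # every voxel label resolves to exactly one property entry
  expect_true(all(as.vector(g100$label) %in% g100$props$label))
  expect_false(any(duplicated(g100$props$label)))
  # stratum corneum occupies exactly one voxel row per side at matching pitch
  g_fine <- build_voxel_model(finger_geometry(voxel_pitch = 0.02,
                                              lateral_extent = 1),
                              pressure = 100)
  sc <- which(g_fine$props$name == "stratum_corneum")
  sc_rows <- which(apply(g_fine$label == sc, 2, any))
  expect_identical(sc_rows, c(1L, ncol(g_fine$label)))
  # total depth = mirrored stack + bone + two artery bands, within one pitch
  lay <- finger_layer_properties(940)
  band <- artery_diameter(200) + 0.4
  expected <- 2 * (sum(lay$thickness) - 2) + 2 + 2 * band
  expect_lt(abs(g_fine$total_thickness - expected), 3 * 0.02 + 0.1)
  # artery voxel count is non-decreasing in pressure
  counts <- vapply(c(42, 80, 120, 160, 200), function(p)
    artery_voxel_count(build_voxel_model(geom, pressure = p)), 1)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
  # determinism: identical inputs -> identical grids
  g2 <- build_voxel_model(geom, pressure = 100, wavelength_nm = 940)
  expect_identical(g100$label, g2$label)
  expect_warning(build_voxel_model(geom, pressure = 30), "outside")
  # lumen/wall mode labels both artery media
  gl <- build_voxel_model(finger_geometry(voxel_pitch = 0.05,
                                          lateral_extent = 4,
                                          artery_mode = "lumen_wall"),
                          pressure = 100)
  expect_setequal(
    intersect(c("artery_lumen", "artery_wall"), gl$props$name),
    c("artery_lumen", "artery_wall"))
  expect_true(all(c("artery_lumen", "artery_wall") %in%
                    gl$props$name[match(unique(as.vector(gl$label)),
                                        gl$props$label)]))
})
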