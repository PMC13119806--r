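test_that("equivalent radius: closed form and monotonicity", {
  expect_equal(equivalent_radius(pi), 1)
  expect_equal(equivalent_radius(100), sqrt(100 / pi))
  expect_equal(round(equivalent_radius(100), 4), 5.6419)
  a <- sort(runif(20, 1, 500))
  expect_true(all(diff(equivalent_radius(a)) > 0))
  expect_error(equivalent_radius(0), "positive")
})

test_that("single-vessel conductivity: hand value and quartic scaling", {
  expect_equal(single_vessel_conductivity(0), 0)
  # r = 6 um, eta = 1.002e-3 Pa s, l = 0.02 m
  k <- single_vessel_conductivity(6e-6, 1.002e-3, 0.02)
  expect_equal(k, pi * (6e-6)^4 / (8 * 1.002e-3 * 0.02))
  expect_equal(signif(k, 4), 2.540e-17)
  expect_equal(single_vessel_conductivity(12e-6, 1.002e-3, 0.02), 16 * k)
  expect_error(single_vessel_conductivity(6e-6, 0), "positive")
})

test_that("water viscosity matches reference values", {
  expect_equal(water_viscosity(20), 1.002e-3, tolerance = 0.002)
  expect_equal(water_viscosity(25), 0.890e-3, tolerance = 0.002)
})

test_that("leaf Kmax matches an independent unit-conversion oracle", {
  # 50 identical vessels of radius 6 um, A = 0.003 m2, l = 0.02 m, 25 C.
  # Oracle assembled step by step, independently of leaf_kmax():
  eta <- 2.414e-5 * 10^(247.8 / (25 + 273.15 - 140))
  ki <- pi * (6e-6)^4 / (8 * eta * 0.02)      # m3 s-1 Pa-1
  k_si <- 50 * ki / 0.003                      # m3 s-1 Pa-1 per m2 leaf
  # / molar volume -> mol, * 1e3 -> mmol, * 1e6 -> per MPa
  oracle <- (k_si / 1.8e-5) * 1e3 * 1e6
  an <- vessel_anatomy(rep(pi * 6^2, 50), n_total = 50, leaf_area = 0.003,
                       petiole_length = 0.02, water_temperature = 25)
  expect_equal(as.numeric(leaf_kmax(an)), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(leaf_kmax(an)), 26.46, tolerance = 0.001)
})

test_that("Kmax is linear in N, inverse in A, order-invariant", {
  areas <- pi * c(5.5, 6.2, 4.9, 7.1, 6.0)^2
  base <- vessel_anatomy(areas, n_total = 6)
  dblN <- vessel_anatomy(areas, n_total = 12)
  # doubling N drops the counted fraction below 2/3, which (correctly)
  # warns; the linearity property is what is under test here
  expect_equal(suppressWarnings(as.numeric(leaf_kmax(dblN))),
               2 * as.numeric(leaf_kmax(base)))
  halfA <- vessel_anatomy(areas, n_total = 6, leaf_area = 0.0015)
  expect_equal(as.numeric(leaf_kmax(halfA)), 2 * as.numeric(leaf_kmax(base)))
  perm <- vessel_anatomy(rev(areas), n_total = 6)
  expect_equal(as.numeric(leaf_kmax(perm)), as.numeric(leaf_kmax(base)))
})

test_that("Kmax shrinks under drought-like vessel atrophy", {
  an <- generate_vessel_anatomy(seed = 3)
  shrunk <- vessel_anatomy(an$vessel_areas * 0.8^2, an$n_total,
                           an$leaf_area, an$petiole_length,
                           an$water_temperature)
  expect_lt(as.numeric(leaf_kmax(shrunk)), as.numeric(leaf_kmax(an)))
})

test_that("under-sampled vessel counts warn per the protocol rule", {
  an <- vessel_anatomy(pi * c(30, 35, 40), n_total = 10)
  expect_warning(leaf_kmax(an), "two-thirds")
})

test_that("relative water content: bounds, clipping and errors", {
  expect_equal(relative_water_content(2.0, 2.0, 1.0), 1)
  expect_equal(relative_water_content(1.0, 2.0, 1.0), 0)
  expect_equal(relative_water_content(1.8, 2.0, 1.0), 0.8)
  expect_warning(r <- relative_water_content(2.005, 2.0, 1.0), "clipped")
  expect_equal(r, 1)
  expect_error(relative_water_content(2.5, 2.0, 1.0), "more than 1%")
  expect_error(relative_water_content(1.5, 1.0, 2.0), "exceed")
})

test_that("humidity-difference helper is positive and increases with dryness", {
  d50 <- absolute_humidity_difference(25, 25, 0.5)
  d90 <- absolute_humidity_difference(25, 25, 0.9)
  expect_gt(d50, d90)
  expect_gt(d90, 0)
  # saturated air at equal temperature: no gradient
  expect_equal(absolute_humidity_difference(25, 25, 1), 0)
})
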