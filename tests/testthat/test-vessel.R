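test_that("Moens-Korteweg PWV matches the closed form", {
  expect_equal(moens_korteweg_pwv(1e6, 1e-3, 1090, 0.01), 9.578263,
               tolerance = 1e-6)
  # sqrt scaling: quadrupling E doubles c
  expect_equal(moens_korteweg_pwv(4e6, 1e-3, 1090, 0.01),
               2 * moens_korteweg_pwv(1e6, 1e-3, 1090, 0.01))
  # identity case E h = rho D
  expect_equal(moens_korteweg_pwv(1090, 1, 1090, 1), 1)
  expect_error(moens_korteweg_pwv(-1, 1, 1, 1), "> 0")
})

test_that("superposition delay is the aortic round trip", {
  net <- toy_network(aorta_len = 2.0)
  expect_equal(superposition_delay(net), 2 * 2.0 / 18)   # 0.2222 s
  physio <- vessel_network(tube_segment(0.5, 5), tube_segment(0.55, 10), 1e8,
                           measurement_site_m = 0.5)
  expect_equal(superposition_delay(physio), 0.2)
  expect_equal(superposition_delay(toy_network(aorta_len = 4.0)),
               2 * superposition_delay(net))
})

test_that("mock-length design rule reproduces the loop dimensions", {
  expect_equal(design_mock_length(0.5, 5, 18, "nearest_integer_ratio"), 2.0)
  expect_equal(design_mock_length(0.55, 10, 21, "nearest_integer_ratio"), 1.1)
  expect_equal(design_mock_length(0.5, 10, 21, "nearest_integer_ratio"), 1.0)
  expect_equal(design_mock_length(0.5, 5, 18, "none"), 1.8)
  expect_error(design_mock_length(0, 5, 18), "> 0")
})

test_that("exact scaling preserves the superposition delay; rounding stays within 12%", {
  real <- vessel_network(tube_segment(0.5, 5), tube_segment(0.55, 10), 1e8,
                         measurement_site_m = 0.5)
  exact_len <- design_mock_length(0.5, 5, 18, "none")
  mock_exact <- vessel_network(tube_segment(exact_len, 18),
                               tube_segment(1.0, 21), 1e8)
  expect_identical(superposition_delay(mock_exact), superposition_delay(real))
  rounded_len <- design_mock_length(0.5, 5, 18, "nearest_integer_ratio")
  mock_round <- vessel_network(tube_segment(rounded_len, 18),
                               tube_segment(1.0, 21), 1e8)
  rel <- abs(superposition_delay(mock_round) - superposition_delay(real)) /
    superposition_delay(real)
  expect_lt(rel, 0.12)
})

test_that("characteristic impedance is rho c / A with linear scaling", {
  expect_equal(characteristic_impedance(1090, 18, 3.14e-4), 6.2484e7,
               tolerance = 1e-4)
  expect_equal(characteristic_impedance(1, 1, 1), 1)
  expect_equal(characteristic_impedance(1090, 36, 3.14e-4),
               2 * characteristic_impedance(1090, 18, 3.14e-4))
  expect_error(characteristic_impedance(1090, 0, 1), "> 0")
})

test_that("segment and network invariants are enforced", {
  expect_error(tube_segment(-1, 18), "length_m")
  expect_error(tube_segment(1, 0), "pwv")
  # stated PWV must agree with Moens-Korteweg when wall properties are given
  expect_error(tube_segment(1, 18, inner_diameter_m = 0.01,
                            wall_thickness_m = 1e-3, elastic_modulus_Pa = 1e6,
                            density_kg_per_m3 = 1090),
               "Moens-Korteweg")
  ok <- tube_segment(1, 9.5783, inner_diameter_m = 0.01,
                     wall_thickness_m = 1e-3, elastic_modulus_Pa = 1e6,
                     density_kg_per_m3 = 1090)
  expect_s3_class(ok, "tube_segment")
  expect_error(vessel_network(tube_segment(2, 18), tube_segment(1, 21), -1),
               "peripheral_resistance")
  expect_error(vessel_network(tube_segment(2, 18), tube_segment(1, 21), 1e8,
                              measurement_site_m = 2), "radial segment")
})
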