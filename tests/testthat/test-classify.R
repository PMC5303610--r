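test_that("CFS arithmetic and antisymmetry", {
  flat <- ph_curve(1:8 * 50, rep(10, 8))
  expect_equal(cfs(flat), 0)
  curve <- ph_curve(1:5 * 50, c(30, 28, 20, 8, 4))
  expect_equal(cfs(curve), 23)
  # reversing the first five amplitudes flips the sign
  set.seed(42)
  for (k in 1:20) {
    y <- runif(5, 0, 40)
    fwd <- ph_curve(1:5 * 50, y)
    rev_ <- ph_curve(1:5 * 50, rev(y))
    expect_equal(cfs(rev_), -cfs(fwd))
  }
  expect_error(cfs(ph_curve(1:4 * 50, rep(1, 4))), "5 hold-down steps")
})

test_that("depth labels follow the CFS threshold", {
  expect_identical(classify_depth(23), "floating")
  expect_identical(classify_depth(2), "normal")
  expect_identical(classify_depth(-17.5), "sunken")
  expect_identical(classify_depth(15), "normal")    # boundary is exclusive
  expect_identical(classify_depth(8, alpha = 5), "floating")
  expect_error(classify_depth(0, alpha = -1), "alpha")
})

test_that("rate labels use the 60 and 90 bpm set points", {
  expect_identical(classify_rate(60), "slow")
  expect_identical(classify_rate(75), "normal")
  expect_identical(classify_rate(90), "rapid")
  # measured rates are rounded to whole bpm first
  expect_identical(classify_rate(60.3), "slow")
  expect_identical(classify_rate(89.7), "rapid")
  expect_identical(classify_rate(61), "normal")
  expect_error(classify_rate(0), "beat_rate")
})

test_that("pulse force and power follow the P-H curve geometry", {
  flat <- ph_curve(c(50, 150, 250), rep(8, 3))
  expect_equal(pulse_force(flat), 8)
  expect_equal(pulse_power(flat), 8 * 200)     # height times span
  doubled <- ph_curve(flat$applied_pressure_mmHg, 2 * flat$amplitude_mmHg)
  expect_equal(pulse_force(doubled), 2 * pulse_force(flat))
  expect_equal(pulse_power(doubled), 2 * pulse_power(flat))
})

test_that("strength labels compare the force against a reference", {
  expect_identical(classify_strength(40, 40), "normal")
  expect_identical(classify_strength(55, 40), "replete")
  expect_identical(classify_strength(25, 40), "vacuous")
  expect_identical(classify_strength(49, 40), "normal")  # inside 25% band
  expect_error(classify_strength(1, 0), "reference_force")
})

test_that("shape rule combines arrival timing and incisura height", {
  mk <- function(arr, inc) {
    structure(list(reflected_arrival_s = arr, incisura_relative_height = inc),
              class = "pulse_features")
  }
  ts <- 0.256
  expect_identical(classify_shape(mk(0.178, 0.7), ts), "string_like")
  expect_identical(classify_shape(mk(0.267, 0.05), ts), "slippery")
  expect_identical(classify_shape(mk(0.222, 0.3), ts), "normal")
  # advanced arrival but low incisura is not string-like
  expect_identical(classify_shape(mk(0.178, 0.2), ts), "normal")
  # arrival at the reference delay is normal even with a high incisura
  expect_identical(classify_shape(mk(0.222, 0.8), 0.32), "normal")
  expect_identical(classify_shape(mk(NA_real_, NA_real_), ts), "normal")
})

test_that("CFS of the depth presets respects the +/-15 decision band", {
  cf <- vapply(c("floating", "normal", "sunken"),
               function(nm) cfs(measure_ph_curve(cached_wave(nm))), numeric(1))
  expect_gt(cf[["floating"]], 15)
  expect_lt(cf[["sunken"]], -15)
  expect_lt(abs(cf[["normal"]]), 15)
})

test_that("each preset is labelled on its own axis and normal elsewhere", {
  expected <- list(
    normal      = c("normal", "normal", "normal", "normal"),
    floating    = c("floating", "normal", "normal", "normal"),
    sunken      = c("sunken", "normal", "normal", "normal"),
    slow        = c("normal", "slow", "normal", "normal"),
    rapid       = c("normal", "rapid", "normal", "normal"),
    slippery    = c("normal", "normal", "slippery", "normal"),
    string_like = c("normal", "normal", "string_like", "normal"),
    vacuous     = c("normal", "normal", "normal", "vacuous"),
    replete     = c("normal", "normal", "normal", "replete"))
  for (nm in names(expected)) {
    rep <- cached_report(nm)
    got <- c(rep$depth_label, rep$rate_label, rep$shape_label,
             rep$strength_label)
    expect_identical(got, expected[[nm]], label = nm)
  }
})

test_that("string-like and slippery presets separate on incisura height", {
  f_str <- cached_report("string_like")$features
  f_slip <- cached_report("slippery")$features
  expect_gte(f_str$incisura_relative_height, 0.5)
  expect_lte(f_slip$incisura_relative_height, 0.25)
})

test_that("replete exceeds normal exceeds vacuous in pulse force", {
  f <- vapply(c("vacuous", "normal", "replete"),
              function(nm) pulse_force(measure_ph_curve(cached_wave(nm))),
              numeric(1))
  expect_true(f[["vacuous"]] < f[["normal"]] && f[["normal"]] < f[["replete"]])
})
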