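test_that("reflection coefficient spans matched to closed terminations", {
  expect_equal(reflection_coefficient(1, 1), 0)
  expect_equal(reflection_coefficient(1e12, 1), 1, tolerance = 1e-9)
  expect_equal(reflection_coefficient(3, 1), 0.5)
  expect_equal(reflection_coefficient(0, 1), -1)
  expect_error(reflection_coefficient(1, 0), "Z_c")
})

test_that("delay-line solution matches the finite-difference wave oracle", {
  # single uniform segment, flow-source inlet, resistive end: the d'Alembert
  # superposition must agree with an independent grid solution of the linear
  # 1-D wave equation to within 2% RMS of the pulse amplitude
  crank <- crank_config()
  T <- beat_period(crank)
  qbar <- stroke_volume(crank) / T
  qt <- function(tt) ejection_flow(tt, crank) - qbar
  L <- 2.0
  cc <- 18
  Zc <- 4e7
  for (gamma in c(0.9, -0.5)) {
    fd <- fd_wave_pressure(qt, L, cc, Zc, gamma, duration = 2.4)
    dl <- Zc * (qt(fd$t) + gamma * qt(fd$t - 2 * L / cc))
    sel <- fd$t >= 2.4 - T       # steady-state beat
    rms <- sqrt(mean((fd$p[sel] - dl[sel])^2)) /
      (max(dl[sel]) - min(dl[sel]))
    expect_lt(rms, 0.02)
  }
})

test_that("matched termination without rebound leaves the pure forward wave", {
  crank <- crank_config()
  fl <- fluid_spec()
  area <- pi * (0.025 / 2)^2
  zc <- characteristic_impedance(1000 * mixture_density(fl), 18, area)
  net <- vessel_network(tube_segment(2, 18, inner_diameter_m = 0.025),
                        tube_segment(1, 21),
                        peripheral_resistance_Pa_s_per_m3 = zc,
                        measurement_site_m = 0.8)
  cfg <- simulation_config(crank = crank, network = net, fluid = fl,
                           valve_rebound_fraction = 0, impedance_scale = 1)
  w <- simulate_radial_pressure(cfg)
  tau <- 2 / 18 + 0.8 / 21
  qbar <- stroke_volume(crank) / beat_period(crank)
  expected <- zc * (ejection_flow(w$time_s - tau, crank) - qbar) / 133.322
  expect_equal(w$pressure_mmHg - mean(w$pressure_mmHg),
               expected - mean(expected), tolerance = 1e-9)
})

test_that("cycle-mean pressure equals venous pressure plus R_p times mean flow", {
  for (nm in c("normal", "floating", "rapid", "replete")) {
    cfg <- preset_config(nm)
    w <- cached_wave(nm)
    qbar <- stroke_volume(cfg$crank) / beat_period(cfg$crank)
    expected <- cfg$venous_pressure_mmHg +
      cfg$network$peripheral_resistance_Pa_s_per_m3 * qbar / 133.322
    expect_equal(wave_mean(w), expected, tolerance = 0.01)
  }
})

test_that("the waveform is periodic after the first two beats", {
  w <- cached_wave("normal")
  fs <- w$sample_rate_Hz
  T <- 0.8
  i1 <- seq.int(round(2 * T * fs) + 1, round(3 * T * fs))
  i2 <- i1 + round(T * fs)
  expect_equal(w$pressure_mmHg[i1], w$pressure_mmHg[i2], tolerance = 1e-9)
})

test_that("presets encode the manipulated variable of each pulse type", {
  expect_equal(preset_config("slow")$crank$rpm, 60)
  expect_equal(preset_config("rapid")$crank$rpm, 90)
  expect_equal(preset_config("slippery")$network$aorta$length_m, 2.4)
  expect_equal(preset_config("string_like")$network$aorta$length_m, 1.6)
  expect_equal(stroke_volume(preset_config("vacuous")$crank) * 1e6, 40)
  expect_equal(stroke_volume(preset_config("replete")$crank) * 1e6, 80)
  expect_error(preset_config("bounding"), "unknown preset")
  expect_length(preset_names(), 9)
})

test_that("depth presets shift the mean at constant pulse pressure", {
  m <- vapply(c("floating", "normal", "sunken"),
              function(nm) wave_mean(cached_wave(nm)), numeric(1))
  expect_true(m[["floating"]] < m[["normal"]] & m[["normal"]] < m[["sunken"]])
  pp <- vapply(c("floating", "normal", "sunken"),
               function(nm) wave_pulse_pressure(cached_wave(nm)), numeric(1))
  expect_lt(diff(range(pp)) / mean(pp), 0.05)
})

test_that("strength presets change pulse pressure at constant mean", {
  pp <- vapply(c("vacuous", "normal", "replete"),
               function(nm) wave_pulse_pressure(cached_wave(nm)), numeric(1))
  expect_true(pp[["vacuous"]] < pp[["normal"]] & pp[["normal"]] < pp[["replete"]])
  m <- vapply(c("vacuous", "normal", "replete"),
              function(nm) wave_mean(cached_wave(nm)), numeric(1))
  expect_lt(diff(range(m)) / mean(m), 0.02)
})

test_that("shape presets move the superposition timing around systole", {
  d_slip <- superposition_delay(preset_config("slippery")$network)
  d_norm <- superposition_delay(preset_config("normal")$network)
  d_str <- superposition_delay(preset_config("string_like")$network)
  expect_equal(d_slip / d_str, 1.5)
  ts <- systole_duration(preset_config("normal")$crank)
  expect_lt(d_str, ts)     # advanced arrival inside ejection
  expect_gt(d_slip, ts)    # delayed arrival after ejection
  expect_lt(d_norm, ts)
})

test_that("configuration invariants are enforced", {
  net <- toy_network()
  expect_error(simulation_config(network = net, duration_s = 1),
               "3 beats")
  expect_error(simulation_config(network = net, sample_rate_Hz = 100),
               "sample_rate")
  expect_error(simulation_config(network = net, valve_rebound_fraction = 0.9),
               "valve_rebound_fraction")
  expect_error(simulation_config(network = net, n_reflections = 0),
               "n_reflections")
  # aorta without a diameter cannot form an impedance
  bad_net <- vessel_network(tube_segment(2, 18), tube_segment(1, 21), 1e8)
  expect_error(simulate_radial_pressure(simulation_config(network = bad_net)),
               "inner_diameter_m")
})
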