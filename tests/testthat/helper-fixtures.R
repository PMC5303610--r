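# Shared fixtures. Preset simulations are deterministic, so waveforms and
# derived quantities are memoised across test files.
.sim_cache <- new.env(parent = emptyenv())

cached_wave <- function(name) {
  if (is.null(.sim_cache[[name]])) {
    .sim_cache[[name]] <- simulate_preset(name)
  }
  .sim_cache[[name]]
}

cached_report <- function(name) {
  key <- paste0("report_", name)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- classify_preset(name, reference_force = normal_force())
  }
  .sim_cache[[key]]
}

normal_force <- function() {
  if (is.null(.sim_cache$normal_force)) {
    .sim_cache$normal_force <-
      pulse_force(measure_ph_curve(cached_wave("normal")))
  }
  .sim_cache$normal_force
}

# Small vessel network used by unit tests that do not need the presets.
toy_network <- function(rp = 2e8, aorta_len = 2.0) {
  vessel_network(
    aorta = tube_segment(aorta_len, 18, inner_diameter_m = 0.025),
    radial = tube_segment(1.0, 21),
    peripheral_resistance_Pa_s_per_m3 = rp,
    measurement_site_m = 0.8)
}

# Synthetic periodic waveform built from per-beat bump components.
toy_wave <- function(freq_hz = 1.25, duration = 8, fs = 500, mean = 100,
                     amp = 15) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  pressure_waveform(t, mean + amp * sin(2 * pi * freq_hz * t))
}

# Trapezoidal quadrature used as the independent integration route.
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
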