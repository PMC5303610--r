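#' Uniformly sampled pressure waveform
#'
#' Pressure time series at the radial measurement site.
#'
#' @param time_s Strictly increasing, uniformly spaced times in seconds.
#' @param pressure_mmHg Pressures in mmHg; finite, same length as `time_s`.
#' @param sample_rate_Hz Sampling rate; inferred from `time_s` when missing.
#' @return An object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(time_s, pressure_mmHg, sample_rate_Hz = NULL) {
  if (length(time_s) != length(pressure_mmHg)) {
    stop("time and pressure must have equal length", call. = FALSE)
  }
  if (length(time_s) < 3L) {
    stop("waveform too short for analysis (need >= 3 samples)", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("time grid must be uniform; resample first", call. = FALSE)
  }
  if (!all(is.finite(pressure_mmHg))) {
    stop("pressure values must be finite", call. = FALSE)
  }
  if (is.null(sample_rate_Hz)) sample_rate_Hz <- 1 / mean(dt)
  structure(list(time_s = as.numeric(time_s),
                 pressure_mmHg = as.numeric(pressure_mmHg),
                 sample_rate_Hz = sample_rate_Hz),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(paste0("<pressure_waveform> %d samples at %g Hz (%.3g s), ",
                     "mean %.4g mmHg, pulse pressure %.4g mmHg\n"),
              length(x$time_s), x$sample_rate_Hz,
              length(x$time_s) / x$sample_rate_Hz,
              wave_mean(x), wave_pulse_pressure(x)))
  invisible(x)
}

#' @export
plot.pressure_waveform <- function(x, ...) {
  plot(x$time_s, x$pressure_mmHg, type = "l",
       xlab = "time (s)", ylab = "pressure (mmHg)", ...)
  invisible(x)
}

#' Mean and pulse pressure of a waveform
#'
#' @param wave A [pressure_waveform()].
#' @return `wave_mean()` the time-averaged pressure; `wave_pulse_pressure()`
#'   the peak-to-peak excursion, both in mmHg.
#' @export
wave_mean <- function(wave) mean(wave$pressure_mmHg)

#' @rdname wave_mean
#' @export
wave_pulse_pressure <- function(wave) {
  max(wave$pressure_mmHg) - min(wave$pressure_mmHg)
}

#' Full simulation configuration
#'
#' Aggregates pump, vessel network and working fluid with the simulation
#' controls of the delay-line wave model.
#'
#' @param crank A [crank_config()].
#' @param network A [vessel_network()]; the aorta segment needs an inner
#'   diameter so its characteristic impedance can be formed.
#' @param fluid A [fluid_spec()].
#' @param duration_s Simulated duration; at least 3 beats.
#' @param sample_rate_Hz Output sampling rate, >= 200 Hz. Default 1000.
#' @param valve_rebound_fraction Amplitude of the post-closure rebound
#'   (dicrotic) transient relative to the forward-wave pulse amplitude, in
#'   `[0, 0.5]`. Default 0.1.
#' @param n_reflections Number of reflected-wave terms retained (>= 1).
#'   Default 2: deeper re-reflections in the physical loop are strongly
#'   damped, and the undamped delay line represents that by truncation.
#' @param venous_pressure_mmHg Constant back-pressure of the reservoirs.
#' @param heart_reflection Reflection coefficient of the closed inlet valve
#'   applied to re-reflections, in `[0, 1)`. Default 0.5 (lumped valve and
#'   viscous losses).
#' @param impedance_scale Dimensionless calibration factor multiplying the
#'   physical characteristic impedance `rho c / A`; see
#'   [calibrate_impedance_scale()].
#' @param rebound_width_s,rebound_decay_s Width (half-sine lobe) and decay
#'   time of the rebound transient, seconds.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(crank = crank_config(),
                              network,
                              fluid = fluid_spec(),
                              duration_s = 8,
                              sample_rate_Hz = 1000,
                              valve_rebound_fraction = 0.1,
                              n_reflections = 2,
                              venous_pressure_mmHg = 5,
                              heart_reflection = 0.5,
                              impedance_scale = 1,
                              rebound_width_s = 0.12,
                              rebound_decay_s = 0.06) {
  stopifnot(inherits(crank, "crank_config"), inherits(network, "vessel_network"),
            inherits(fluid, "fluid_spec"))
  if (duration_s < 3 * beat_period(crank)) {
    stop("duration_s must cover at least 3 beats", call. = FALSE)
  }
  if (sample_rate_Hz < 200) stop("sample_rate_Hz must be >= 200", call. = FALSE)
  if (n_reflections < 1) stop("n_reflections must be >= 1", call. = FALSE)
  if (valve_rebound_fraction < 0 || valve_rebound_fraction > 0.5) {
    stop("valve_rebound_fraction must lie in [0, 0.5]", call. = FALSE)
  }
  if (heart_reflection < 0 || heart_reflection >= 1) {
    stop("heart_reflection must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(crank = crank, network = network, fluid = fluid,
         duration_s = duration_s, sample_rate_Hz = sample_rate_Hz,
         valve_rebound_fraction = valve_rebound_fraction,
         n_reflections = n_reflections,
         venous_pressure_mmHg = venous_pressure_mmHg,
         heart_reflection = heart_reflection,
         impedance_scale = impedance_scale,
         rebound_width_s = rebound_width_s,
         rebound_decay_s = rebound_decay_s),
    class = "simulation_config")
}

#' Reflection coefficient of a resistive termination
#'
#' `Gamma = (R_p - Z_c) / (R_p + Z_c)`, in `[-1, 1]`: 0 for a matched
#' termination, +1 for a closed end (infinite resistance), -1 for an open end.
#'
#' @param R_p Terminal resistance, Pa s/m^3, >= 0.
#' @param Z_c Characteristic impedance, Pa s/m^3, > 0.
#' @return Dimensionless reflection coefficient.
#' @examples
#' reflection_coefficient(3, 1)  # 0.5
#' @export
reflection_coefficient <- function(R_p, Z_c) {
  if (any(Z_c <= 0)) stop("Z_c must be > 0", call. = FALSE)
  if (any(R_p < 0)) stop("R_p must be >= 0", call. = FALSE)
  (R_p - Z_c) / (R_p + Z_c)
}

# Effective (calibrated) aortic characteristic impedance of a configuration.
config_impedance <- function(cfg) {
  a <- cfg$network$aorta
  if (is.null(a$inner_diameter_m)) {
    stop("aorta segment needs inner_diameter_m to form its impedance",
         call. = FALSE)
  }
  area <- pi * (a$inner_diameter_m / 2)^2
  cfg$impedance_scale *
    characteristic_impedance(fluid_density_si(cfg$fluid), a$pwv_m_per_s, area)
}

#' Simulate the radial-artery pressure waveform
#'
#' Linear delay-line (d'Alembert) superposition model of the loop. The pump
#' flow `Q(t)` is split into its cycle mean and zero-mean pulsatile part; the
#' mean sets the operating pressure through the peripheral resistance
#' (`P_mean = P_venous + R_p Qbar`), while the pulsatile part launches a
#' forward wave of amplitude `Z_c Qtilde` that arrives at the measurement
#' site after the transit delay and is followed by `n_reflections` reflected
#' copies, each a further superposition delay (`2 L_aorta / c_aorta`) later
#' and attenuated by the peripheral reflection coefficient (and by the
#' closed-valve heart-end coefficient for re-reflections). A damped half-sine
#' rebound transient is injected at each valve closure, giving the incisura
#' and dicrotic wave. The simulation is deterministic.
#'
#' @param cfg A [simulation_config()].
#' @return A [pressure_waveform()].
#' @export
simulate_radial_pressure <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  crank <- cfg$crank
  net <- cfg$network
  T <- beat_period(crank)
  fs <- cfg$sample_rate_Hz
  n <- round(cfg$duration_s * fs)
  t <- seq_len(n) / fs - 1 / fs

  Zc <- config_impedance(cfg)
  Rp <- net$peripheral_resistance_Pa_s_per_m3
  gamma <- reflection_coefficient(Rp, Zc)
  gh <- cfg$heart_reflection
  if (abs(gamma * gh) >= 1) {
    stop("unstable configuration: |Gamma * Gamma_heart| >= 1", call. = FALSE)
  }

  qbar <- stroke_volume(crank) / T
  qtilde <- function(tt) ejection_flow(tt, crank) - qbar

  tau_f <- net$aorta$length_m / net$aorta$pwv_m_per_s +
    net$measurement_site_m / net$radial$pwv_m_per_s
  dt_sup <- superposition_delay(net)

  k <- 1 / MMHG_PA
  p <- cfg$venous_pressure_mmHg + Rp * qbar * k + Zc * k * qtilde(t - tau_f)
  for (j in seq_len(cfg$n_reflections)) {
    coef <- gamma^j * gh^(j - 1)
    p <- p + Zc * k * coef * qtilde(t - tau_f - j * dt_sup)
  }

  if (cfg$valve_rebound_fraction > 0) {
    # peak forward flow (analytic over one beat on a fine grid)
    qmax <- max(ejection_flow(seq(0, T, length.out = 4001), crank))
    amp <- cfg$valve_rebound_fraction * Zc * k * qmax
    w <- cfg$rebound_width_s
    # beat-relative time since the valve-closure signal reached the site
    v <- (t - tau_f - systole_duration(crank)) %% T
    reb <- ifelse(v <= w, amp * sin(pi * v / w) * exp(-v / cfg$rebound_decay_s), 0)
    p <- p + reb
  }

  pressure_waveform(t, p, fs)
}

#' Calibrate the impedance scale against a target pulse pressure
#'
#' The loop's absolute pressure level and pulsatility are set by two
#' calibration constants: the peripheral resistance (fixing the cycle-mean
#' pressure analytically) and a dimensionless factor on the aortic
#' characteristic impedance (fixing the pulse pressure, solved numerically
#' here). These are properties of the simulated bench loop, chosen once; the
#' packaged presets use the frozen result (see [preset_config()]).
#'
#' @param cfg A [simulation_config()]; its `impedance_scale` is ignored.
#' @param target_pp_mmHg Desired pulse pressure of the simulated waveform.
#' @param interval Search interval for the scale factor.
#' @return The scale factor as a single number.
#' @export
calibrate_impedance_scale <- function(cfg, target_pp_mmHg = 40,
                                      interval = c(0.01, 2)) {
  f <- function(s) {
    cfg$impedance_scale <- s
    wave_pulse_pressure(simulate_radial_pressure(cfg)) - target_pp_mmHg
  }
  uniroot(f, interval = interval, tol = 1e-6)$root
}
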