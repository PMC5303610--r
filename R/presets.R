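# Loop calibration constants. The simulated bench loop runs, like its
# physical counterpart, at pressures well above physiological values (stiff
# silicone tubes; the hold-down protocol spans 50-400 mmHg and the P-H peak
# of the normal state sits mid-range). These are properties of the simulator,
# chosen once, not measured quantities of any subject:
#   - normal cycle-mean pressure 145 mmHg (near the centre of hold-down
#     steps 1-5, ~150.6 mmHg, so the normal P-H peak is centred); floating /
#     sunken shift the mean by -60 / +60 mmHg via the peripheral resistance
#     alone;
#   - normal pulse pressure 40 mmHg, realised by .IMPEDANCE_SCALE on the
#     physical aortic characteristic impedance (frozen output of
#     calibrate_impedance_scale() on the normal preset).
.MEAN_TARGETS <- c(normal = 145, floating = 85, sunken = 205)
.VENOUS_MMHG <- 5
.IMPEDANCE_SCALE <- 0.3508076

# Geometry shared by all presets (aorta diameter only enters through the
# impedance, which is rescaled by the calibration anyway).
.AORTA_D <- 0.025

.PRESET_NAMES <- c("normal", "floating", "sunken", "slow", "rapid",
                   "slippery", "string_like", "vacuous", "replete")

# Peripheral resistance that realises a target cycle-mean pressure for a
# given pump: mean = venous + R_p * Qbar.
.rp_for_mean <- function(mean_mmHg, crank) {
  qbar <- stroke_volume(crank) / beat_period(crank)
  (mean_mmHg - .VENOUS_MMHG) * MMHG_PA / qbar
}

#' Names of the built-in pulse-type presets
#'
#' @return Character vector of the nine preset names.
#' @export
preset_names <- function() .PRESET_NAMES

#' Built-in simulation presets for the nine pulse types
#'
#' Returns a fully specified [simulation_config()] for one of the nine pulse
#' types studied on the loop. Each preset differs from `normal` only in the
#' manipulated variable(s) of its axis:
#' \describe{
#'   \item{normal}{75 bpm, 60 mL stroke volume, 2.0 m aorta at 18 m/s,
#'     1.0 m radial at 21 m/s, peripheral resistance set for a 150 mmHg
#'     cycle-mean.}
#'   \item{floating / sunken}{peripheral resistance lowered / raised to move
#'     the cycle-mean pressure to 90 / 210 mmHg; nothing else changes.}
#'   \item{slow / rapid}{crank speed 60 / 90 rpm; resistance unchanged.}
#'   \item{slippery / string_like}{aorta length 2.4 / 1.6 m, delaying /
#'     advancing the reflected wave; nothing else changes.}
#'   \item{vacuous / replete}{crank radius 0.02 / 0.04 m (stroke volume 40 /
#'     80 mL) with the peripheral resistance re-solved so the cycle-mean
#'     pressure stays at 150 mmHg: pulse pressure changes at constant mean.}
#' }
#'
#' @param name One of [preset_names()].
#' @param duration_s,sample_rate_Hz Simulation controls (defaults 8 s,
#'   1000 Hz; 8 s covers a whole number of beats at 60, 75 and 90 bpm).
#' @return A [simulation_config()].
#' @examples
#' preset_config("slow")$crank$rpm  # 60
#' @export
preset_config <- function(name, duration_s = 8, sample_rate_Hz = 1000) {
  if (length(name) != 1L || !name %in% .PRESET_NAMES) {
    stop(sprintf("unknown preset '%s'; see preset_names()", name),
         call. = FALSE)
  }
  crank <- crank_config()
  aorta_len <- 2.0
  mean_target <- .MEAN_TARGETS[["normal"]]

  if (name %in% c("floating", "sunken")) {
    mean_target <- .MEAN_TARGETS[[name]]
  } else if (name == "slow") {
    crank <- crank_config(rpm = 60)
  } else if (name == "rapid") {
    crank <- crank_config(rpm = 90)
  } else if (name == "slippery") {
    aorta_len <- 2.4
  } else if (name == "string_like") {
    aorta_len <- 1.6
  } else if (name == "vacuous") {
    crank <- crank_config(crank_radius_m = 0.02)
  } else if (name == "replete") {
    crank <- crank_config(crank_radius_m = 0.04)
  }

  # rate presets keep the normal-pulse resistance fixed (only rpm varies);
  # all others (re-)solve R_p for their target mean
  rp <- if (name %in% c("slow", "rapid")) {
    .rp_for_mean(.MEAN_TARGETS[["normal"]], crank_config())
  } else {
    .rp_for_mean(mean_target, crank)
  }

  net <- vessel_network(
    aorta = tube_segment(aorta_len, 18, inner_diameter_m = .AORTA_D),
    radial = tube_segment(1.0, 21),
    peripheral_resistance_Pa_s_per_m3 = rp,
    measurement_site_m = 0.8)

  simulation_config(crank = crank, network = net, fluid = fluid_spec(),
                    duration_s = duration_s, sample_rate_Hz = sample_rate_Hz,
                    impedance_scale = .IMPEDANCE_SCALE)
}

#' Simulate a preset in one call
#'
#' @inheritParams preset_config
#' @return A [pressure_waveform()].
#' @export
simulate_preset <- function(name, duration_s = 8, sample_rate_Hz = 1000) {
  simulate_radial_pressure(preset_config(name, duration_s, sample_rate_Hz))
}
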