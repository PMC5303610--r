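#' Tonometric hold-down protocol
#'
#' The stepped-weight measurement: identical weights are stacked on a
#' pressing pad of known contact area, so each step adds `m g / A` of applied
#' surface pressure. With the default 60 g unit and 0.88 cm^2 pad each step
#' is about 50 mmHg, spanning roughly 50-400 mmHg over eight steps.
#'
#' @param unit_mass_kg Mass of one weight, kg. Default 0.060.
#' @param contact_area_m2 Pad-vessel contact area, m^2. Default 0.88e-4.
#' @param n_steps Number of cumulative steps, >= 5 (the CFS needs the first
#'   five amplitudes). Default 8.
#' @param gravity_m_per_s2 Gravitational acceleration. Default 9.81.
#' @return An object of class `tonometry_protocol`.
#' @export
tonometry_protocol <- function(unit_mass_kg = 0.060, contact_area_m2 = 0.88e-4,
                               n_steps = 8, gravity_m_per_s2 = 9.81) {
  if (any(c(unit_mass_kg, contact_area_m2, n_steps, gravity_m_per_s2) <= 0)) {
    stop("all protocol parameters must be > 0", call. = FALSE)
  }
  if (n_steps < 5) stop("n_steps must be >= 5 (CFS needs Y1..Y5)", call. = FALSE)
  structure(list(unit_mass_kg = unit_mass_kg,
                 contact_area_m2 = contact_area_m2,
                 n_steps = as.integer(n_steps),
                 gravity_m_per_s2 = gravity_m_per_s2),
            class = "tonometry_protocol")
}

#' Applied surface pressure at a hold-down step
#'
#' `step * m * g / A`, converted to mmHg.
#'
#' @param step Step index (1-based), within the protocol's range.
#' @param proto A [tonometry_protocol()].
#' @return Applied pressure in mmHg.
#' @examples
#' applied_pressure(1, tonometry_protocol())  # ~50 mmHg
#' applied_pressure(8, tonometry_protocol())  # ~400 mmHg
#' @export
applied_pressure <- function(step, proto = tonometry_protocol()) {
  stopifnot(inherits(proto, "tonometry_protocol"))
  if (any(step < 1 | step > proto$n_steps | step != round(step))) {
    stop(sprintf("step must be an integer in 1..%d", proto$n_steps),
         call. = FALSE)
  }
  step * proto$unit_mass_kg * proto$gravity_m_per_s2 /
    proto$contact_area_m2 / MMHG_PA
}

#' Transmitted pulse amplitude under an applied pressure
#'
#' Tonometric transfer model: the pulse amplitude felt through the vessel
#' wall is maximal when the applied pressure equals the mean intravascular
#' pressure and falls off with transmural pressure magnitude on either side.
#' `H = PP(wave) * T(P_applied - P_mean)` with a Gaussian transfer
#' `T(d) = exp(-d^2 / (2 width^2))`: unimodal, symmetric, `T(0) = 1`. Raising
#' the waveform's mean therefore slides the P-H curve rigidly along the
#' applied-pressure axis, and scaling its pulsatile component scales H
#' without moving the peak.
#'
#' @param wave A [pressure_waveform()].
#' @param P_applied Applied pressure(s), mmHg.
#' @param transfer_width_mmHg Gaussian width of the transfer function, mmHg.
#'   Default 80.
#' @return Amplitude(s) H in mmHg.
#' @export
transmitted_amplitude <- function(wave, P_applied, transfer_width_mmHg = 80) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (transfer_width_mmHg <= 0) {
    stop("transfer_width_mmHg must be > 0", call. = FALSE)
  }
  pp <- wave_pulse_pressure(wave)
  d <- P_applied - wave_mean(wave)
  pp * exp(-d^2 / (2 * transfer_width_mmHg^2))
}

#' P-H curve container
#'
#' Paired applied pressures (strictly increasing) and measured pulse
#' amplitudes (non-negative).
#'
#' @param applied_pressure_mmHg Ascending applied pressures.
#' @param amplitude_mmHg Pulse amplitudes H, same length.
#' @param step_index Optional step indices (default 1..n).
#' @return An object of class `ph_curve`.
#' @export
ph_curve <- function(applied_pressure_mmHg, amplitude_mmHg,
                     step_index = seq_along(applied_pressure_mmHg)) {
  if (length(applied_pressure_mmHg) != length(amplitude_mmHg)) {
    stop("applied pressures and amplitudes must have equal length",
         call. = FALSE)
  }
  if (any(diff(applied_pressure_mmHg) <= 0)) {
    stop("applied pressures must be strictly increasing", call. = FALSE)
  }
  if (any(amplitude_mmHg < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(applied_pressure_mmHg = as.numeric(applied_pressure_mmHg),
                 amplitude_mmHg = as.numeric(amplitude_mmHg),
                 step_index = as.integer(step_index)),
            class = "ph_curve")
}

#' @export
print.ph_curve <- function(x, ...) {
  cat(sprintf("<ph_curve> %d steps, force %.4g mmHg at %g mmHg applied\n",
              length(x$step_index), max(x$amplitude_mmHg),
              x$applied_pressure_mmHg[which.max(x$amplitude_mmHg)]))
  invisible(x)
}

#' @export
plot.ph_curve <- function(x, ...) {
  plot(x$applied_pressure_mmHg, x$amplitude_mmHg, type = "b",
       xlab = "applied pressure (mmHg)", ylab = "pulse amplitude H (mmHg)", ...)
  invisible(x)
}

#' Measure a P-H curve from a waveform
#'
#' Runs the stepped hold-down protocol on a simulated (or imported) waveform:
#' at each step the applied pressure is [applied_pressure()] and the
#' amplitude is [transmitted_amplitude()]. An optional measurement-noise hook
#' adds i.i.d. Gaussian noise to the amplitudes under an explicit seed (the
#' default protocol is exact and deterministic).
#'
#' @inheritParams transmitted_amplitude
#' @param proto A [tonometry_protocol()].
#' @param noise_sd Standard deviation of optional amplitude noise, mmHg.
#' @param seed Seed used when `noise_sd > 0` (required then).
#' @return A [ph_curve()].
#' @examples
#' \donttest{
#' curve <- measure_ph_curve(simulate_preset("normal"))
#' cfs(curve)
#' }
#' @export
measure_ph_curve <- function(wave, proto = tonometry_protocol(),
                             transfer_width_mmHg = 80,
                             noise_sd = 0, seed = NULL) {
  stopifnot(inherits(wave, "pressure_waveform"),
            inherits(proto, "tonometry_protocol"))
  steps <- seq_len(proto$n_steps)
  p_app <- applied_pressure(steps, proto)
  h <- transmitted_amplitude(wave, p_app, transfer_width_mmHg)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("noise_sd > 0 requires an explicit seed",
                            call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    h <- pmax(0, h + rnorm(length(h), sd = noise_sd))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  ph_curve(p_app, h, steps)
}
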