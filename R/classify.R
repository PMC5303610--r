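#' Coefficient of floating and sunken pulse (CFS)
#'
#' `CFS = (Y1 + Y2)/2 - (Y4 + Y5)/2`, where `Yk` is the pulse amplitude at
#' hold-down step k. A floating pulse (peak amplitude at light hold-down) has
#' a large positive CFS; a sunken pulse (peak at heavy hold-down) a negative
#' one.
#'
#' @param curve A [ph_curve()] with at least 5 steps.
#' @return The CFS value in mmHg.
#' @examples
#' cfs(ph_curve(1:5 * 50, c(30, 28, 20, 8, 4)))  # 23
#' @export
cfs <- function(curve) {
  stopifnot(inherits(curve, "ph_curve"))
  y <- curve$amplitude_mmHg
  if (length(y) < 5L) stop("CFS needs at least 5 hold-down steps", call. = FALSE)
  (y[1L] + y[2L]) / 2 - (y[4L] + y[5L]) / 2
}

#' Depth classification from the CFS
#'
#' Floating if `CFS > alpha`, sunken if `CFS < -alpha`, otherwise normal.
#' The decision constant alpha defaults to 15.
#'
#' @param cfs_value CFS value.
#' @param alpha Positive decision threshold.
#' @return `"floating"`, `"normal"` or `"sunken"`.
#' @export
classify_depth <- function(cfs_value, alpha = 15) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (cfs_value > alpha) "floating"
  else if (cfs_value < -alpha) "sunken"
  else "normal"
}

#' Rate classification
#'
#' Slow at or below `slow_bpm`, rapid at or above `rapid_bpm`. The measured
#' rate is first rounded to the nearest whole beat per minute (the precision
#' at which pulse rates are stated), so a detected 59.99 bpm still counts as
#' the 60 bpm set point.
#'
#' @param beat_rate_bpm Measured beat rate, > 0.
#' @param slow_bpm,rapid_bpm Set points; defaults 60 and 90.
#' @return `"slow"`, `"normal"` or `"rapid"`.
#' @export
classify_rate <- function(beat_rate_bpm, slow_bpm = 60, rapid_bpm = 90) {
  if (beat_rate_bpm <= 0) stop("beat_rate_bpm must be > 0", call. = FALSE)
  r <- round(beat_rate_bpm)
  if (r <= slow_bpm) "slow" else if (r >= rapid_bpm) "rapid" else "normal"
}

#' Shape classification from superposition timing and incisura height
#'
#' The string-like and slippery shapes are driven by the arrival time of the
#' reflected wave: advanced arrival (short aorta) superposes within systole
#' and props up the incisura; delayed arrival (long aorta) lands in diastole,
#' leaving a low incisura and a prominent diastolic wave. Because a slow or
#' rapid pulse rescales the whole beat, arrival *relative to systole* cannot
#' separate a short aorta from a slow heart; the classifier therefore also
#' compares the absolute arrival against a reference superposition delay
#' (that of the normal 2.0 m / 18 m/s aorta by default, analogous to the
#' reference force of [classify_strength()]).
#'
#' Labelled string-like when the arrival is advanced relative to the
#' reference (ratio below `1 - arrival_tolerance`), falls within systole and
#' the incisura is high; slippery when the arrival is delayed (ratio above
#' `1 + arrival_tolerance`), falls after systole and the incisura is low;
#' otherwise normal.
#'
#' @param features A [extract_features()] result.
#' @param systole_duration_s Ejection duration of the beat, seconds.
#' @param reference_arrival_s Reference superposition delay, seconds.
#'   Default `2 * 2.0 / 18`.
#' @param arrival_tolerance Relative dead-band around the reference.
#' @param incisura_high,incisura_low Relative-height thresholds defining a
#'   "high" and "low" incisura. Defaults 0.5 and 0.25.
#' @return `"string_like"`, `"normal"` or `"slippery"`.
#' @export
classify_shape <- function(features, systole_duration_s,
                           reference_arrival_s = 2 * 2.0 / 18,
                           arrival_tolerance = 0.1,
                           incisura_high = 0.5, incisura_low = 0.25) {
  stopifnot(inherits(features, "pulse_features"))
  arr <- features$reflected_arrival_s
  inc <- features$incisura_relative_height
  if (is.na(arr)) return("normal")
  ratio <- arr / reference_arrival_s
  if (ratio <= 1 - arrival_tolerance && arr <= systole_duration_s &&
      !is.na(inc) && inc >= incisura_high) {
    "string_like"
  } else if (ratio >= 1 + arrival_tolerance && arr > systole_duration_s &&
             (is.na(inc) || inc <= incisura_low)) {
    "slippery"
  } else {
    "normal"
  }
}

#' Pulse force and pulse power of a P-H curve
#'
#' Strength indices: the pulse force is the maximum amplitude of the P-H
#' curve; the pulse power is the trapezoidal area under the curve over the
#' measured applied-pressure range (no extrapolation beyond it).
#'
#' @param curve A [ph_curve()].
#' @return `pulse_force()` in mmHg; `pulse_power()` in mmHg^2.
#' @export
pulse_force <- function(curve) {
  stopifnot(inherits(curve, "ph_curve"))
  max(curve$amplitude_mmHg)
}

#' @rdname pulse_force
#' @export
pulse_power <- function(curve) {
  stopifnot(inherits(curve, "ph_curve"))
  x <- curve$applied_pressure_mmHg
  y <- curve$amplitude_mmHg
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Strength classification against a reference force
#'
#' Replete when the pulse force exceeds the reference by more than the
#' tolerance fraction, vacuous when it falls short by more than it,
#' otherwise normal.
#'
#' @param force Measured pulse force, mmHg.
#' @param reference_force Reference (normal-state) pulse force, > 0.
#' @param tolerance_fraction Relative dead-band. Default 0.25.
#' @return `"vacuous"`, `"normal"` or `"replete"`.
#' @export
classify_strength <- function(force, reference_force,
                              tolerance_fraction = 0.25) {
  if (reference_force <= 0) stop("reference_force must be > 0", call. = FALSE)
  if (force > (1 + tolerance_fraction) * reference_force) "replete"
  else if (force < (1 - tolerance_fraction) * reference_force) "vacuous"
  else "normal"
}

#' Classify a pulse on all four axes
#'
#' Runs the full quantification: waveform features, CFS, depth / rate /
#' shape / strength labels, pulse force and power.
#'
#' @param wave A [pressure_waveform()].
#' @param curve The waveform's [ph_curve()].
#' @param reference_force Normal-state pulse force used by the strength rule.
#' @param systole_duration_s Ejection duration; when `NULL`, the incisura
#'   time of the averaged beat is used as its estimate.
#' @param reflected_delay_s Optional known superposition delay, passed to
#'   [extract_features()].
#' @param alpha Depth threshold, see [classify_depth()].
#' @param ... Further arguments passed to [classify_shape()].
#' @return An object of class `pulse_report`.
#' @examples
#' \donttest{
#' wave <- simulate_preset("floating")
#' curve <- measure_ph_curve(wave)
#' ref <- pulse_force(measure_ph_curve(simulate_preset("normal")))
#' classify_pulse(wave, curve, ref)$depth_label  # "floating"
#' }
#' @export
classify_pulse <- function(wave, curve, reference_force,
                           systole_duration_s = NULL,
                           reflected_delay_s = NULL, alpha = 15, ...) {
  feats <- extract_features(wave, reflected_delay_s = reflected_delay_s)
  if (is.null(systole_duration_s)) {
    systole_duration_s <- feats$incisura_time_s
  }
  cfs_val <- cfs(curve)
  force <- pulse_force(curve)
  structure(
    list(depth_label = classify_depth(cfs_val, alpha),
         cfs_value = cfs_val,
         rate_label = classify_rate(feats$beat_rate_bpm),
         shape_label = classify_shape(feats, systole_duration_s, ...),
         strength_label = classify_strength(force, reference_force),
         pulse_force_mmHg = force,
         pulse_power_mmHg2 = pulse_power(curve),
         features = feats),
    class = "pulse_report")
}

#' @export
print.pulse_report <- function(x, ...) {
  cat("<pulse_report>\n")
  cat(sprintf("  depth   : %-11s (CFS %.3g)\n", x$depth_label, x$cfs_value))
  cat(sprintf("  rate    : %-11s (%.1f bpm)\n", x$rate_label,
              x$features$beat_rate_bpm))
  cat(sprintf("  shape   : %s\n", x$shape_label))
  cat(sprintf("  strength: %-11s (force %.4g mmHg, power %.4g mmHg^2)\n",
              x$strength_label, x$pulse_force_mmHg, x$pulse_power_mmHg2))
  invisible(x)
}

#' Run the full pipeline on a preset
#'
#' Simulates the preset, measures its P-H curve and classifies it against the
#' normal preset's pulse force, supplying the model-known superposition delay
#' and systole duration to the feature extractor.
#'
#' @inheritParams preset_config
#' @param reference_force Reference force; computed from the normal preset
#'   when `NULL`.
#' @return A `pulse_report`.
#' @export
classify_preset <- function(name, reference_force = NULL) {
  cfg <- preset_config(name)
  wave <- simulate_radial_pressure(cfg)
  curve <- measure_ph_curve(wave)
  if (is.null(reference_force)) {
    reference_force <- pulse_force(measure_ph_curve(simulate_preset("normal")))
  }
  classify_pulse(wave, curve, reference_force,
                 systole_duration_s = systole_duration(cfg$crank),
                 reflected_delay_s = superposition_delay(cfg$network))
}
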