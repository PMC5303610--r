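#' Elastic tube segment
#'
#' One segment of the mock arterial tree: a thin-walled elastic tube with a
#' length and a pulse wave velocity. Wall properties are optional; when
#' elastic modulus, wall thickness and inner diameter are all supplied the
#' stated PWV is checked against the Moens-Korteweg value (within 1%) using
#' the supplied or default fluid density.
#'
#' @param length_m Segment length in metres.
#' @param pwv_m_per_s Pulse wave velocity c in m/s.
#' @param inner_diameter_m Optional lumen diameter D in metres.
#' @param wall_thickness_m Optional wall thickness h in metres.
#' @param elastic_modulus_Pa Optional wall elastic modulus E in pascals.
#' @param density_kg_per_m3 Fluid density used only for the consistency check
#'   when E, h and D are all given. Default 1090 (glycerin-water blood
#'   analogue).
#' @return An object of class `tube_segment`.
#' @export
tube_segment <- function(length_m, pwv_m_per_s, inner_diameter_m = NULL,
                         wall_thickness_m = NULL, elastic_modulus_Pa = NULL,
                         density_kg_per_m3 = 1090) {
  if (!(is.numeric(length_m) && length_m > 0)) {
    stop("length_m must be > 0", call. = FALSE)
  }
  if (!(is.numeric(pwv_m_per_s) && pwv_m_per_s > 0)) {
    stop("pwv_m_per_s must be > 0", call. = FALSE)
  }
  has_wall <- !is.null(inner_diameter_m) && !is.null(wall_thickness_m) &&
    !is.null(elastic_modulus_Pa)
  if (has_wall) {
    c_mk <- moens_korteweg_pwv(elastic_modulus_Pa, wall_thickness_m,
                               density_kg_per_m3, inner_diameter_m)
    if (abs(c_mk - pwv_m_per_s) / pwv_m_per_s > 0.01) {
      stop(sprintf(paste0("stated PWV %.3g m/s inconsistent with ",
                          "Moens-Korteweg value %.3g m/s (>1%%)"),
                   pwv_m_per_s, c_mk), call. = FALSE)
    }
  }
  structure(
    list(length_m = length_m, pwv_m_per_s = pwv_m_per_s,
         inner_diameter_m = inner_diameter_m,
         wall_thickness_m = wall_thickness_m,
         elastic_modulus_Pa = elastic_modulus_Pa),
    class = "tube_segment")
}

#' @export
print.tube_segment <- function(x, ...) {
  cat(sprintf("<tube_segment> L = %g m, c = %g m/s", x$length_m, x$pwv_m_per_s))
  if (!is.null(x$inner_diameter_m)) cat(sprintf(", D = %g m", x$inner_diameter_m))
  cat("\n")
  invisible(x)
}

#' Two-segment vessel network with peripheral termination
#'
#' The mock arterial tree: an aorta segment whose distal end is the main
#' reflection site, a radial segment branching at that end carrying the wave
#' to the tonometry site, and a lumped peripheral resistance terminating the
#' loop. The aorta-radial junction is treated as impedance matched (the bench
#' loop used brachial-artery dimensions to balance the flow split), so
#' reflection happens only against the peripheral resistance.
#'
#' @param aorta,radial [tube_segment()] objects.
#' @param peripheral_resistance_Pa_s_per_m3 Terminal resistance R_p >= 0.
#' @param measurement_site_m Distance of the measurement point from the
#'   aorta-radial junction along the radial segment; must lie on the segment.
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(aorta, radial, peripheral_resistance_Pa_s_per_m3,
                           measurement_site_m = 0.8) {
  stopifnot(inherits(aorta, "tube_segment"), inherits(radial, "tube_segment"))
  if (!(is.numeric(peripheral_resistance_Pa_s_per_m3) &&
        peripheral_resistance_Pa_s_per_m3 >= 0)) {
    stop("peripheral_resistance_Pa_s_per_m3 must be >= 0", call. = FALSE)
  }
  if (!(measurement_site_m >= 0 && measurement_site_m <= radial$length_m)) {
    stop("measurement_site_m must lie within the radial segment",
         call. = FALSE)
  }
  structure(
    list(aorta = aorta, radial = radial,
         peripheral_resistance_Pa_s_per_m3 = peripheral_resistance_Pa_s_per_m3,
         measurement_site_m = measurement_site_m),
    class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network>\n")
  cat(sprintf("  aorta : L = %g m, c = %g m/s\n",
              x$aorta$length_m, x$aorta$pwv_m_per_s))
  cat(sprintf("  radial: L = %g m, c = %g m/s (site at %g m)\n",
              x$radial$length_m, x$radial$pwv_m_per_s, x$measurement_site_m))
  cat(sprintf("  R_p   : %.4g Pa s/m^3\n", x$peripheral_resistance_Pa_s_per_m3))
  cat(sprintf("  superposition delay: %.4g s\n", superposition_delay(x)))
  invisible(x)
}

#' Moens-Korteweg pulse wave velocity
#'
#' `c = sqrt(E h / (rho D))` for a thin-walled elastic tube: lets users derive
#' a segment PWV from tube specifications instead of measuring it.
#'
#' @param E Wall elastic modulus in Pa.
#' @param h Wall thickness in m.
#' @param density Fluid density in kg/m^3.
#' @param D Lumen inner diameter in m.
#' @return PWV in m/s.
#' @examples
#' moens_korteweg_pwv(1e6, 1e-3, 1090, 0.01)  # 9.578 m/s
#' @export
moens_korteweg_pwv <- function(E, h, density, D) {
  if (any(c(E, h, density, D) <= 0)) {
    stop("all Moens-Korteweg arguments must be > 0", call. = FALSE)
  }
  sqrt(E * h / (density * D))
}

#' Superposition delay of the main reflected wave
#'
#' Round-trip travel time from the aorta-radial junction to the main
#' reflection site at the distal end of the aorta and back:
#' `2 L_aorta / c_aorta`. This is the delay between the forward wave and the
#' reflected wave at the measurement site (reflection distance times the
#' inverse of the pulse wave velocity, each way).
#'
#' @param net A [vessel_network()].
#' @return Delay in seconds.
#' @examples
#' net <- vessel_network(tube_segment(2, 18), tube_segment(1, 21), 1e8)
#' superposition_delay(net)  # 0.2222 s
#' @export
superposition_delay <- function(net) {
  stopifnot(inherits(net, "vessel_network"))
  2 * net$aorta$length_m / net$aorta$pwv_m_per_s
}

#' Mock-loop tube length from the superposition-time design rule
#'
#' The bench loop uses stiffer tubes than human arteries, so waves travel
#' faster; to preserve the superposition time of the reflected wave the tube
#' must be lengthened by the PWV ratio. `real_length * mock_pwv / real_pwv`,
#' with the ratio optionally rounded to the nearest integer (as the physical
#' loop did: 18/5 -> 4 for the aorta, 21/10 -> 2 for the arm).
#'
#' @param real_length_m Physiological segment length in m.
#' @param real_pwv Physiological PWV in m/s.
#' @param mock_pwv Mock-tube PWV in m/s.
#' @param rounding `"none"` (preserve the delay exactly) or
#'   `"nearest_integer_ratio"`.
#' @return Mock tube length in metres.
#' @examples
#' design_mock_length(0.5, 5, 18, "nearest_integer_ratio")  # 2 m
#' design_mock_length(0.5, 5, 18, "none")                   # 1.8 m
#' @export
design_mock_length <- function(real_length_m, real_pwv, mock_pwv,
                               rounding = c("none", "nearest_integer_ratio")) {
  rounding <- match.arg(rounding)
  if (any(c(real_length_m, real_pwv, mock_pwv) <= 0)) {
    stop("all design inputs must be > 0", call. = FALSE)
  }
  ratio <- mock_pwv / real_pwv
  if (rounding == "nearest_integer_ratio") ratio <- round(ratio)
  real_length_m * ratio
}

#' Characteristic impedance of a tube
#'
#' `Z_c = rho c / A`: the ratio of pulsatile pressure to pulsatile flow
#' carried by a unidirectional wave; couples the pump flow to pressure and
#' sets the reflection coefficient against the peripheral resistance.
#'
#' @param density Fluid density in kg/m^3.
#' @param c PWV in m/s.
#' @param lumen_area_m2 Lumen cross-sectional area in m^2.
#' @return Impedance in Pa s/m^3.
#' @examples
#' characteristic_impedance(1090, 18, 3.14e-4)
#' @export
characteristic_impedance <- function(density, c, lumen_area_m2) {
  if (any(c(density, c, lumen_area_m2) <= 0)) {
    stop("all impedance arguments must be > 0", call. = FALSE)
  }
  density * c / lumen_area_m2
}
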