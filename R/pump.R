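#' Slider-crank pump configuration
#'
#' Geometry and drive speed of the piston pump that plays the left ventricle.
#' A crank of radius `r` turns at `rpm` revolutions per minute (one revolution
#' = one beat) and drives a piston of area `A_p` through a connecting rod of
#' length `l`; the swept (stroke) volume is `2 r A_p`.
#'
#' The advancing (ejection) stroke is completed in a fraction
#' `systole_fraction` of the beat and the return stroke in the remainder, as
#' if the crank angle were driven through a two-speed cam. `systole_fraction
#' = 0.5` recovers the constant-angular-velocity crank. The default 0.32
#' gives an ejection window of 0.26 s at 75 bpm, scaling with the period, so
#' that the reflected wave of the default 2 m / 18 m/s aorta (round-trip
#' 0.222 s) arrives within systole at 60 bpm but in diastole at 90 bpm.
#'
#' @param crank_radius_m Crank radius r in metres. Default 0.03 m which,
#'   together with the default piston area, realises a 60 mL stroke volume.
#' @param rod_length_m Connecting-rod length l in metres; must exceed the
#'   crank radius.
#' @param piston_area_m2 Piston cross-sectional area in square metres.
#' @param rpm Crank rotation rate (= beats per minute). Default 75.
#' @param systole_fraction Fraction of the beat occupied by the advancing
#'   (ejection) stroke, in (0, 1).
#' @return An object of class `crank_config`.
#' @examples
#' cfg <- crank_config()
#' stroke_volume(cfg) * 1e6   # mL per beat
#' @export
crank_config <- function(crank_radius_m = 0.03, rod_length_m = 0.12,
                         piston_area_m2 = 1e-3, rpm = 75,
                         systole_fraction = 0.32) {
  stopifnot(is.numeric(crank_radius_m), length(crank_radius_m) == 1L,
            is.numeric(rod_length_m), length(rod_length_m) == 1L,
            is.numeric(piston_area_m2), length(piston_area_m2) == 1L,
            is.numeric(rpm), length(rpm) == 1L,
            is.numeric(systole_fraction), length(systole_fraction) == 1L)
  if (!(crank_radius_m > 0)) {
    stop("invalid pump geometry: crank_radius_m must be > 0", call. = FALSE)
  }
  if (!(rod_length_m > crank_radius_m)) {
    stop("invalid pump geometry: rod_length_m must exceed crank_radius_m",
         call. = FALSE)
  }
  if (!(piston_area_m2 > 0)) {
    stop("invalid pump geometry: piston_area_m2 must be > 0", call. = FALSE)
  }
  if (!(rpm > 0)) stop("rpm must be > 0", call. = FALSE)
  if (!(systole_fraction > 0 && systole_fraction < 1)) {
    stop("systole_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(crank_radius_m = crank_radius_m, rod_length_m = rod_length_m,
         piston_area_m2 = piston_area_m2, rpm = rpm,
         systole_fraction = systole_fraction),
    class = "crank_config")
}

#' @export
print.crank_config <- function(x, ...) {
  cat("<crank_config>\n")
  cat(sprintf("  crank radius : %g m\n", x$crank_radius_m))
  cat(sprintf("  rod length   : %g m\n", x$rod_length_m))
  cat(sprintf("  piston area  : %g m^2\n", x$piston_area_m2))
  cat(sprintf("  speed        : %g rpm (period %.4g s)\n", x$rpm, beat_period(x)))
  cat(sprintf("  stroke volume: %g mL, systole fraction %g\n",
              stroke_volume(x) * 1e6, x$systole_fraction))
  invisible(x)
}

#' Beat period and stroke volume of a pump configuration
#'
#' @param cfg A [crank_config()].
#' @return `beat_period()` the period 60/rpm in seconds; `stroke_volume()` the
#'   swept volume `2 r A_p` in cubic metres.
#' @export
beat_period <- function(cfg) 60 / cfg$rpm

#' @rdname beat_period
#' @export
stroke_volume <- function(cfg) 2 * cfg$crank_radius_m * cfg$piston_area_m2

#' Piston position of the slider-crank mechanism
#'
#' Distance from the crank axis to the piston pin,
#' `x(theta) = r cos(theta) + sqrt(l^2 - r^2 sin^2 theta)`, periodic in 2*pi
#' and bounded in `[l - r, l + r]` (bottom / top dead centre).
#'
#' @param theta Crank angle(s) in radians.
#' @param cfg A [crank_config()].
#' @return Piston displacement(s) in metres.
#' @examples
#' piston_position(0, crank_config())      # top dead centre, r + l
#' piston_position(pi, crank_config())     # bottom dead centre, l - r
#' @export
piston_position <- function(theta, cfg) {
  stopifnot(inherits(cfg, "crank_config"))
  r <- cfg$crank_radius_m
  l <- cfg$rod_length_m
  r * cos(theta) + sqrt(l^2 - r^2 * sin(theta)^2)
}

# d x / d theta, used by the flow model and the inverse kinematics.
piston_velocity_dtheta <- function(theta, cfg) {
  r <- cfg$crank_radius_m
  l <- cfg$rod_length_m
  -r * sin(theta) * (1 + r * cos(theta) / sqrt(l^2 - r^2 * sin(theta)^2))
}

#' Inverse slider-crank kinematics
#'
#' Crank angle at which the piston sits at displacement `x`, on the requested
#' half-cycle. On the advancing half (`theta` in `[0, pi]`) the piston moves
#' from top dead centre (`x = l + r`) to bottom dead centre (`x = l - r`);
#' the returning half is its mirror image in `[pi, 2 pi]`. Solved by
#' root-finding to a displacement tolerance below 1e-9 m.
#'
#' @param x Piston displacement(s) in metres, within `[l - r, l + r]`.
#' @param cfg A [crank_config()].
#' @param branch `"advancing"` or `"returning"` half-cycle.
#' @return Crank angle(s) in radians.
#' @examples
#' cfg <- crank_config()
#' inverse_crank_angle(cfg$rod_length_m + cfg$crank_radius_m, cfg)  # 0
#' @export
inverse_crank_angle <- function(x, cfg, branch = c("advancing", "returning")) {
  stopifnot(inherits(cfg, "crank_config"))
  branch <- match.arg(branch)
  r <- cfg$crank_radius_m
  l <- cfg$rod_length_m
  lo <- l - r
  hi <- l + r
  if (any(x < lo - 1e-12 | x > hi + 1e-12)) {
    stop(sprintf("displacement outside reachable range [%g, %g] m", lo, hi),
         call. = FALSE)
  }
  x <- pmin(pmax(x, lo), hi)
  one <- function(xi) {
    if (xi >= hi) return(0)
    if (xi <= lo) return(pi)
    uniroot(function(th) piston_position(th, cfg) - xi,
            interval = c(0, pi), tol = 1e-13)$root
  }
  th <- vapply(x, one, numeric(1))
  if (branch == "returning") th <- 2 * pi - th
  th
}

# Crank angle and angular velocity under the two-speed (cam) drive at times t.
crank_angle_at <- function(t, cfg) {
  T <- beat_period(cfg)
  f <- cfg$systole_fraction
  u <- (t %% T) / T                      # beat phase in [0, 1)
  adv <- u < f
  theta <- ifelse(adv, pi * u / f, pi + pi * (u - f) / (1 - f))
  dtheta_dt <- ifelse(adv, pi / (f * T), pi / ((1 - f) * T))
  list(theta = theta, dtheta_dt = dtheta_dt, advancing = adv)
}

#' Pulsatile ejection flow of the piston pump
#'
#' Instantaneous flow delivered into the arterial side,
#' `Q(t) = A_p * max(0, -dx/dt)`: the outlet check valve passes only the
#' advancing (ejecting) piston motion and closes during the return stroke, so
#' `Q >= 0`, `Q` is periodic with period 60/rpm, and the volume ejected per
#' beat equals the swept volume `2 r A_p` exactly.
#'
#' @param t Time(s) in seconds.
#' @param cfg A [crank_config()].
#' @return Flow(s) in cubic metres per second.
#' @examples
#' cfg <- crank_config()
#' tt <- seq(0, beat_period(cfg), length.out = 2001)
#' # per-beat ejected volume ~ stroke volume (60 mL):
#' sum(diff(tt) * (head(ejection_flow(tt, cfg), -1) +
#'                 tail(ejection_flow(tt, cfg), -1)) / 2) * 1e6
#' @export
ejection_flow <- function(t, cfg) {
  stopifnot(inherits(cfg, "crank_config"))
  ca <- crank_angle_at(t, cfg)
  v <- -piston_velocity_dtheta(ca$theta, cfg) * ca$dtheta_dt  # piston speed into cylinder
  cfg$piston_area_m2 * pmax(0, v)
}

#' Ejection (systole) duration of one beat
#'
#' @param cfg A [crank_config()].
#' @return Duration of the advancing stroke in seconds,
#'   `systole_fraction * 60 / rpm`.
#' @export
systole_duration <- function(cfg) cfg$systole_fraction * beat_period(cfg)
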