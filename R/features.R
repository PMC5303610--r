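#' Waveform feature extraction
#'
#' Beat-level features of a radial pressure waveform: the beat period is
#' detected from the autocorrelation of the detrended signal (global maximum
#' over a plausible lag range, sub-multiple check, parabolic sub-sample
#' refinement); beats after an initial settling window are phase-averaged
#' into one representative beat aligned at its foot (the last near-minimal
#' point before the steepest upstroke); the incisura is the deepest local
#' minimum between the systolic peak and the subsequent dicrotic/reflected
#' peak (falling back to the deepest minimum before 60% of the beat when no
#' secondary peak is present). The reflected-wave
#' arrival is taken from `reflected_delay_s` when the generating model is
#' known, otherwise estimated by shoulder detection on the smoothed fourth
#' derivative of the averaged beat (Savitzky-Golay).
#'
#' @param wave A [pressure_waveform()] covering at least 3 complete beats.
#' @param reflected_delay_s Optional known superposition delay (seconds after
#'   the beat foot), e.g. [superposition_delay()] of the generating network.
#' @param min_bpm,max_bpm Beat-rate search range for period detection.
#' @param settle_beats Beats discarded from the start before averaging.
#' @return An object of class `pulse_features`: a list with
#'   `beat_rate_bpm`, `period_s`, `mean_pressure_mmHg`, `pulse_pressure_mmHg`,
#'   `systolic_peak_time_s`, `incisura_time_s`, `incisura_relative_height`,
#'   `reflected_arrival_s` (all times relative to the beat foot; incisura
#'   fields are `NA` when no interior minimum exists) and `beat` (the
#'   averaged beat as time/pressure vectors).
#' @examples
#' \donttest{
#' f <- extract_features(simulate_preset("normal"),
#'                       reflected_delay_s = 2 * 2.0 / 18)
#' f$beat_rate_bpm
#' }
#' @export
extract_features <- function(wave, reflected_delay_s = NULL,
                             min_bpm = 30, max_bpm = 240, settle_beats = 2) {
  stopifnot(inherits(wave, "pressure_waveform"))
  fs <- wave$sample_rate_Hz
  x <- wave$pressure_mmHg
  n <- length(x)

  period <- detect_period(x, fs, min_bpm, max_bpm)
  if (n / fs < 3 * period) {
    stop("waveform shorter than 3 beats; cannot extract features",
         call. = FALSE)
  }
  beat <- average_beat(wave, period, settle_beats)
  m <- length(beat$pressure)
  du <- period / m
  pk <- which.max(beat$pressure)
  pmin_beat <- min(beat$pressure)
  pp_beat <- max(beat$pressure) - pmin_beat

  # incisura: deepest local minimum between the systolic peak and the
  # following dicrotic/reflected peak (the next local maximum of prominence
  # > 5% PP); when no such secondary peak exists, deepest local minimum up
  # to 60% of the beat
  p <- beat$pressure
  hi <- min(max(pk + 2L, floor(0.6 * m)), m - 1L)
  idx <- seq.int(pk + 1L, hi)
  loc_min <- idx[p[idx] < p[idx - 1L] & p[idx] <= p[idx + 1L]]
  loc_max <- idx[p[idx] > p[idx - 1L] & p[idx] >= p[idx + 1L]]
  if (length(loc_min)) {
    prom <- vapply(loc_max, function(j) p[j] - min(p[pk:j]), numeric(1))
    sec <- loc_max[prom > 0.05 * pp_beat & loc_max > min(loc_min)]
    search <- if (length(sec)) loc_min[loc_min < sec[1L]] else loc_min
    if (!length(search)) search <- loc_min
    inc <- search[which.min(p[search])]
    incisura_time <- (inc - 1L) * du
    incisura_rel <- (p[inc] - pmin_beat) / pp_beat
  } else {
    incisura_time <- NA_real_
    incisura_rel <- NA_real_
  }

  arrival <- if (!is.null(reflected_delay_s)) {
    reflected_delay_s
  } else {
    detect_shoulder(beat$pressure, du, pk)
  }

  structure(
    list(beat_rate_bpm = 60 / period,
         period_s = period,
         mean_pressure_mmHg = wave_mean(wave),
         pulse_pressure_mmHg = pp_beat,
         systolic_peak_time_s = (pk - 1L) * du,
         incisura_time_s = incisura_time,
         incisura_relative_height = incisura_rel,
         reflected_arrival_s = arrival,
         beat = beat),
    class = "pulse_features")
}

#' @export
print.pulse_features <- function(x, ...) {
  cat("<pulse_features>\n")
  cat(sprintf("  beat rate      : %.2f bpm (period %.4g s)\n",
              x$beat_rate_bpm, x$period_s))
  cat(sprintf("  mean / pulse P : %.4g / %.4g mmHg\n",
              x$mean_pressure_mmHg, x$pulse_pressure_mmHg))
  cat(sprintf("  systolic peak  : %.4g s\n", x$systolic_peak_time_s))
  cat(sprintf("  incisura       : %.4g s, relative height %.3g\n",
              x$incisura_time_s, x$incisura_relative_height))
  cat(sprintf("  reflected wave : %.4g s\n", x$reflected_arrival_s))
  invisible(x)
}

# Autocorrelation-based beat period (seconds). Global ACF maximum over the
# lag range, preferring the smallest near-equivalent sub-multiple lag, with
# parabolic interpolation around the discrete peak.
detect_period <- function(x, fs, min_bpm, max_bpm) {
  lag_min <- max(2L, floor(fs * 60 / max_bpm))
  lag_max <- ceiling(fs * 60 / min_bpm)
  if (lag_max + 2L >= length(x)) {
    stop("waveform too short for period detection", call. = FALSE)
  }
  a <- acf(x, lag.max = lag_max + 1L, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # undo the divisor-n finite-sample taper so peaks sit at the true period
  a <- a * length(x) / (length(x) - seq_along(a) + 1L)
  lags <- seq.int(lag_min, lag_max)
  vals <- a[lags + 1L]
  if (max(vals) < 0.2) {
    stop("no periodicity detected in waveform", call. = FALSE)
  }
  best <- lags[which.max(vals)]
  # prefer a sub-multiple if its ACF is nearly as high (harmonic lock guard)
  for (d in 4:2) {
    cand <- round(best / d)
    if (cand >= lag_min && a[cand + 1L] >= 0.9 * a[best + 1L]) {
      best <- cand
      break
    }
  }
  # parabolic sub-sample refinement
  y0 <- a[best]; y1 <- a[best + 1L]; y2 <- a[best + 2L]
  denom <- y0 - 2 * y1 + y2
  frac <- if (abs(denom) > .Machine$double.eps) 0.5 * (y0 - y2) / denom else 0
  frac <- max(-0.5, min(0.5, frac))
  (best + frac) / fs
}

# Phase-average the waveform into one beat aligned at its foot.
average_beat <- function(wave, period, settle_beats) {
  fs <- wave$sample_rate_Hz
  t <- wave$time_s
  total <- t[length(t)] - t[1L]
  nb <- floor((total - settle_beats * period) / period)
  if (nb < 1L) {
    nb <- floor(total / period)
    settle_beats <- 0
  }
  m <- max(16L, round(period * fs))
  u <- (seq_len(m) - 1L) * period / m
  acc <- numeric(m)
  t0 <- t[1L] + settle_beats * period
  for (kk in seq_len(nb)) {
    acc <- acc + approx(t, wave$pressure_mmHg, xout = t0 + (kk - 1L) * period + u,
                        rule = 2)$y
  }
  p <- acc / nb
  # align at the foot: last point at (or within 2% PP of) the pre-upstroke
  # minimum before the steepest circular upstroke
  dp <- diff(c(p, p[1L]))
  i_up <- which.max(dp)
  win <- floor(0.35 * m)
  cand <- ((i_up - win:1 - 1L) %% m) + 1L      # indices preceding the upstroke
  pmin_w <- min(p[cand])
  tol <- 0.02 * (max(p) - min(p))
  near <- cand[p[cand] <= pmin_w + tol]
  # candidate closest (circularly) before the upstroke
  foot <- near[length(near)]
  rot <- c(seq.int(foot, m), if (foot > 1L) seq_len(foot - 1L))
  list(time = u, pressure = p[rot])
}

# Shoulder (reflected-wave arrival) via the smoothed fourth derivative of the
# averaged beat: the arrival produces a local maximum of the fourth
# derivative; take the most prominent one in the search window after the
# early upstroke.
detect_shoulder <- function(p, du, pk) {
  m <- length(p)
  nf <- min(2L * floor(0.03 / du) + 1L, (m %/% 2) * 2 - 1L)
  if (nf < 9L) return(NA_real_)
  p3 <- rep(p, 3L)                              # periodic padding
  d4 <- signal::sgolayfilt(p3, p = 5, n = nf, m = 4, ts = du)
  d4 <- d4[(m + 1L):(2L * m)]
  lo <- min(pk + 2L, m - 3L)
  hi <- min(m - 2L, floor(0.75 * m))
  idx <- seq.int(lo, hi)
  cand <- idx[d4[idx] > d4[idx - 1L] & d4[idx] >= d4[idx + 1L]]
  if (!length(cand)) return(NA_real_)
  (cand[which.max(d4[cand])] - 1L) * du
}
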