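#' Read a pressure waveform from CSV
#'
#' Expects a header `time_s,pressure_mmHg` (UTF-8, '.' decimal separator).
#' Non-numeric fields (including comma decimals) are format errors reported
#' with their line number, as is non-monotone time. Non-uniformly sampled
#' input is resampled onto a uniform grid with a warning.
#'
#' @param path CSV file path.
#' @return A [pressure_waveform()].
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("time_s", "pressure_mmHg")
  if (!all(need %in% names(d))) {
    stop(sprintf("missing column(s): %s (header must be %s)",
                 paste(setdiff(need, names(d)), collapse = ", "),
                 paste(need, collapse = ",")), call. = FALSE)
  }
  if (nrow(d) < 3L) {
    stop("waveform file too short for analysis (need >= 3 rows)", call. = FALSE)
  }
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  for (col in need) {
    bad <- which(!grepl(num_re, trimws(d[[col]])))
    if (length(bad)) {
      stop(sprintf("format error in column '%s' at line %d: '%s' is not a '.'-decimal number",
                   col, bad[1L] + 1L, d[[col]][bad[1L]]), call. = FALSE)
    }
  }
  tt <- as.numeric(d$time_s)
  pp <- as.numeric(d$pressure_mmHg)
  dt <- diff(tt)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone time at line %d", bad[1L] + 2L), call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    warning("non-uniform sampling; resampling to a uniform grid")
    fs <- 1 / stats::median(dt)
    grid <- seq(tt[1L], tt[length(tt)], by = 1 / fs)
    pp <- approx(tt, pp, xout = grid, rule = 2)$y
    tt <- grid
  }
  pressure_waveform(tt, pp)
}

#' Write a pressure waveform to CSV
#'
#' Canonical dialect: header `time_s,pressure_mmHg`, UTF-8, LF line endings,
#' '.' decimal, 12 significant digits (write-read round trips reproduce the
#' values to well below 1e-9).
#'
#' @param wave A [pressure_waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "pressure_waveform"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("time_s,pressure_mmHg",
               sprintf("%.12g,%.12g", wave$time_s, wave$pressure_mmHg)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and write P-H curves as CSV
#'
#' Columns `step,applied_mmHg,amplitude_mmHg`.
#'
#' @param curve A [ph_curve()].
#' @param path File path.
#' @return `read_ph_csv()` a [ph_curve()]; `write_ph_csv()` the path,
#'   invisibly.
#' @export
write_ph_csv <- function(curve, path) {
  stopifnot(inherits(curve, "ph_curve"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("step,applied_mmHg,amplitude_mmHg",
               sprintf("%d,%.12g,%.12g", curve$step_index,
                       curve$applied_pressure_mmHg, curve$amplitude_mmHg)),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ph_csv
#' @export
read_ph_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  d <- read.csv(path)
  need <- c("step", "applied_mmHg", "amplitude_mmHg")
  if (!all(need %in% names(d))) {
    stop(sprintf("missing column(s): %s", paste(setdiff(need, names(d)),
                                                collapse = ", ")), call. = FALSE)
  }
  ph_curve(d$applied_mmHg, d$amplitude_mmHg, d$step)
}

# ---- JSON configuration ----------------------------------------------------

config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  seg <- function(s) {
    out <- list(length_m = s$length_m, pwv_m_per_s = s$pwv_m_per_s)
    for (f in c("inner_diameter_m", "wall_thickness_m", "elastic_modulus_Pa")) {
      if (!is.null(s[[f]])) out[[f]] <- s[[f]]
    }
    out
  }
  list(
    crank = cfg$crank[c("crank_radius_m", "rod_length_m", "piston_area_m2",
                        "rpm", "systole_fraction")],
    network = list(
      aorta = seg(cfg$network$aorta),
      radial = seg(cfg$network$radial),
      peripheral_resistance_Pa_s_per_m3 =
        cfg$network$peripheral_resistance_Pa_s_per_m3,
      measurement_site_m = cfg$network$measurement_site_m),
    fluid = cfg$fluid[c("glycerin_fraction", "temperature_C")],
    duration_s = cfg$duration_s,
    sample_rate_Hz = cfg$sample_rate_Hz,
    valve_rebound_fraction = cfg$valve_rebound_fraction,
    n_reflections = cfg$n_reflections,
    venous_pressure_mmHg = cfg$venous_pressure_mmHg,
    heart_reflection = cfg$heart_reflection,
    impedance_scale = cfg$impedance_scale,
    rebound_width_s = cfg$rebound_width_s,
    rebound_decay_s = cfg$rebound_decay_s)
}

config_from_list <- function(x) {
  need <- c("crank", "network", "fluid")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("config missing field(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  seg <- function(s) do.call(tube_segment, s)
  crank <- do.call(crank_config, x$crank)
  net <- vessel_network(
    aorta = seg(x$network$aorta), radial = seg(x$network$radial),
    peripheral_resistance_Pa_s_per_m3 = x$network$peripheral_resistance_Pa_s_per_m3,
    measurement_site_m = x$network$measurement_site_m)
  extra <- x[setdiff(names(x), c("crank", "network", "fluid"))]
  do.call(simulation_config,
          c(list(crank = crank, network = net,
                 fluid = do.call(fluid_spec, x$fluid)), extra))
}

#' Read and write simulation configurations as JSON
#'
#' The JSON form round-trips losslessly through
#' `read_config_json(write_config_json(cfg, path))`.
#'
#' @param cfg A [simulation_config()].
#' @param path File path.
#' @return `read_config_json()` a [simulation_config()];
#'   `write_config_json()` the path, invisibly.
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(config_to_list(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  config_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run manifest
#'
#' A provenance record for a simulation run: configuration snapshot, package
#' version, timestamp, output paths and optional seed. Serialises to JSON and
#' round-trips losslessly (the timestamp is stored as a formatted string).
#'
#' @param cfg A [simulation_config()].
#' @param outputs Character vector of output file paths.
#' @param seed Optional integer seed.
#' @param timestamp Timestamp string; defaults to the current UTC time.
#' @return An object of class `run_manifest` (a list).
#' @export
run_manifest <- function(cfg, outputs = character(), seed = NULL,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  structure(
    list(config = config_to_list(cfg),
         version = as.character(utils::packageVersion("pulseloop")),
         timestamp = timestamp,
         outputs = as.character(outputs),
         seed = seed),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path File path.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "run_manifest")
}
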