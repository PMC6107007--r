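# Spectral figures of merit for passive radiative cooling: emissivity from
# reflectance and transmittance (1 - R - T), solar-weighted reflectance,
# Planck-weighted thermal emissivity, and the 8-14 um atmospheric-window
# band emissivity.

PLANCK_H <- 6.62607015e-34   # J s
SPEED_C <- 2.99792458e8      # m/s
BOLTZ_K <- 1.380649e-23      # J/K
STEFAN_SIGMA <- 5.670374419e-8  # W m^-2 K^-4

#' Construct an optical spectrum object
#'
#' @param wavelength Strictly increasing wavelength grid (um).
#' @param reflectance,transmittance Dimensionless in [0, 1].
#' @param emissivity Optional; computed by [emissivity_from_RT()] if absent.
#' @return A `spectrum` data-frame-like object.
#' @export
optical_spectrum <- function(wavelength, reflectance, transmittance,
                     emissivity = NULL) {
  stopifnot(length(wavelength) == length(reflectance),
            length(wavelength) == length(transmittance))
  if (anyDuplicated(wavelength) || is.unsorted(wavelength, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing and duplicate-free",
         call. = FALSE)
  }
  if (any(reflectance < -1e-9 | reflectance > 1 + 1e-9) ||
      any(transmittance < -1e-9 | transmittance > 1 + 1e-9)) {
    stop("reflectance and transmittance must lie in [0, 1]", call. = FALSE)
  }
  excess <- reflectance + transmittance - 1
  if (any(excess > 1e-3)) {
    stop_silk(sprintf(
      "R + T exceeds 1 by more than 1e-3 at %d wavelength(s) (max excess %.3g)",
      sum(excess > 1e-3), max(excess)), "silkphotonics_data_error")
  }
  structure(list(wavelength = wavelength, reflectance = reflectance,
                 transmittance = transmittance, emissivity = emissivity),
            class = "spectrum")
}

#' Read a spectrum from CSV
#'
#' Expects the header `wavelength_um,reflectance,transmittance` with an
#' optional fourth `emissivity` column.
#'
#' @param path Path to a CSV file.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) {
    stop(sprintf("could not parse %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  req <- c("wavelength_um", "reflectance", "transmittance")
  if (!all(req %in% names(df))) {
    stop(sprintf("CSV must have columns %s (got: %s)",
                 paste(req, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[req]))
  if (length(bad)) {
    stop(sprintf("malformed CSV: missing values at data line %d", bad[1] + 1L),
         call. = FALSE)
  }
  optical_spectrum(df$wavelength_um, df$reflectance, df$transmittance,
           if ("emissivity" %in% names(df)) df$emissivity else NULL)
}

#' Write a spectrum to CSV
#' @param sp A [spectrum()].
#' @param path Output path.
#' @export
write_spectrum_csv <- function(sp, path) {
  df <- data.frame(wavelength_um = sp$wavelength,
                   reflectance = sp$reflectance,
                   transmittance = sp$transmittance)
  if (!is.null(sp$emissivity)) df$emissivity <- sp$emissivity
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive emissivity as 1 - R - T
#'
#' By Kirchhoff's law for an opaque-plus-transmitting sample, the spectral
#' emissivity equals the absorptance `1 - R - T`. Values outside [0, 1] by
#' at most 1e-3 (instrument noise) are clipped with a warning; larger
#' violations raise a data-quality error.
#'
#' @param sp A [spectrum()].
#' @return The spectrum with the `emissivity` field filled in.
#' @export
emissivity_from_RT <- function(sp) {
  stopifnot(inherits(sp, "spectrum"))
  eps <- 1 - sp$reflectance - sp$transmittance
  out_of_range <- eps < 0 | eps > 1
  if (any(eps < -1e-3)) {
    stop_silk(sprintf(
      "R + T exceeds 1 by more than 1e-3 at %d wavelength(s): data-quality failure",
      sum(eps < -1e-3)), "silkphotonics_data_error")
  }
  if (any(out_of_range)) {
    warning(sprintf("clipped emissivity to [0, 1] at %d wavelength(s)",
                    sum(out_of_range)), call. = FALSE)
    eps <- pmin(1, pmax(0, eps))
  }
  sp$emissivity <- eps
  sp
}

#' Planck hemispherical spectral emissive power
#'
#' Blackbody emissive power per unit wavelength,
#' `E(lambda, T) = 2 pi h c^2 / lambda^5 / (exp(hc / lambda k T) - 1)`,
#' i.e. pi times the spectral radiance, in W m^-2 um^-1. Its integral over
#' all wavelengths is the Stefan-Boltzmann flux `sigma T^4`.
#'
#' @param wavelength Wavelength(s), um.
#' @param temperature Absolute temperature, K (> 0).
#' @return Spectral emissive power, W m^-2 um^-1.
#' @export
planck_spectral_emissive_power <- function(wavelength, temperature) {
  stopifnot(temperature > 0, all(wavelength > 0))
  lam <- wavelength * 1e-6  # m
  e <- 2 * pi * PLANCK_H * SPEED_C^2 / lam^5 /
    (exp(PLANCK_H * SPEED_C / (lam * BOLTZ_K * temperature)) - 1)
  e * 1e-6  # per um instead of per m
}

#' Weight-averaged scalar of a spectral quantity
#'
#' `integral(f * w) / integral(w)` over `bounds`, by trapezoidal quadrature
#' on the union of the spectrum grid and the weight grid. This is the
#' reduction behind "reflectance normalized to the solar spectrum" and
#' "emissivity weighted by the thermal radiation spectrum at 300 K".
#'
#' @param wavelength,values The spectral quantity f(lambda) (um grid).
#' @param weight `"planck"` (thermal radiation at `temperature`) or
#'   `"solar"` (synthetic clear-sky solar weight, see
#'   [synthetic_solar_weight()]), or ignored when `weight_spectrum` given.
#' @param temperature Temperature (K) for the Planck weight.
#' @param bounds Integration bounds `c(lo, hi)` in um; the spectrum must
#'   cover them.
#' @param weight_spectrum Optional user-supplied weight as a list/data frame
#'   with `wavelength` and `weight` columns; takes precedence over `weight`.
#' @return Dimensionless scalar.
#' @export
weighted_scalar <- function(wavelength, values,
                            weight = c("planck", "solar"),
                            temperature = 300, bounds,
                            weight_spectrum = NULL) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (min(wavelength) > bounds[1] + 1e-9 ||
      max(wavelength) < bounds[2] - 1e-9) {
    stop_silk(sprintf(
      "spectrum covers [%.3g, %.3g] um but bounds require [%.3g, %.3g] um: missing %s",
      min(wavelength), max(wavelength), bounds[1], bounds[2],
      if (min(wavelength) > bounds[1]) sprintf("[%.3g, %.3g]", bounds[1], min(wavelength))
      else sprintf("[%.3g, %.3g]", max(wavelength), bounds[2])),
      "silkphotonics_coverage_error")
  }
  if (!is.null(weight_spectrum)) {
    wl_w <- weight_spectrum$wavelength
    w_w <- weight_spectrum$weight
  } else {
    weight <- match.arg(weight)
    if (weight == "planck") {
      wl_w <- seq(bounds[1], bounds[2], length.out = 2048)
      w_w <- planck_spectral_emissive_power(wl_w, temperature)
    } else {
      sw <- synthetic_solar_weight(bounds)
      wl_w <- sw$wavelength; w_w <- sw$weight
    }
  }
  grid <- sort(unique(c(wavelength, wl_w)))
  grid <- grid[grid >= bounds[1] - 1e-12 & grid <= bounds[2] + 1e-12]
  f <- stats::approx(wavelength, values, xout = grid, rule = 2)$y
  w <- stats::approx(wl_w, w_w, xout = grid, rule = 2)$y
  trapz_integral(grid, f * w) / trapz_integral(grid, w)
}

#' Synthetic clear-sky solar weight
#'
#' A download-free stand-in for the AM 1.5 solar spectrum: a 5777 K Planck
#' curve multiplied by a smooth parametric atmospheric-attenuation envelope
#' (logistic UV ozone cutoff plus Gaussian water/CO2 absorption dips near
#' 0.94, 1.13, 1.4, 1.87 and 2.7 um). This reproduces the gross shape of
#' the terrestrial solar spectrum, not its line structure; supply a
#' measured AM 1.5 table via `weight_spectrum` in [weighted_scalar()] or
#' `solar_weight_csv` in [radiometric_summary()] when fidelity matters.
#'
#' @param bounds Wavelength bounds (um), within (0.28, 4.0).
#' @param normalize Scale so the weight integrates to 1 over `bounds`.
#' @return List with `wavelength`, `weight`, and `provenance = "synthetic"`.
#' @export
synthetic_solar_weight <- function(bounds = c(0.28, 4.0), normalize = FALSE) {
  stopifnot(bounds[1] >= 0.28 - 1e-9, bounds[2] <= 4.0 + 1e-9,
            bounds[1] < bounds[2])
  wl <- seq(bounds[1], bounds[2], by = 0.002)
  base <- planck_spectral_emissive_power(wl, 5777)
  dips <- list(c(0.94, 0.035, 0.55), c(1.13, 0.045, 0.65),
               c(1.40, 0.060, 0.92), c(1.87, 0.055, 0.95),
               c(2.70, 0.100, 0.97))
  env <- stats::plogis((wl - 0.31) / 0.012)
  for (d in dips) env <- env * (1 - d[3] * exp(-((wl - d[1]) / d[2])^2))
  w <- pmax(0, base * env)
  if (normalize) w <- w / trapz_integral(wl, w)
  list(wavelength = wl, weight = w, provenance = "synthetic")
}

#' Radiative-cooling figures of merit for a spectrum
#'
#' Reduces a measured or synthetic R/T spectrum to the three scalars used
#' to characterize radiative-cooling textiles: solar-weighted reflectance,
#' Planck-weighted thermal emissivity at `temperature`, and the band
#' emissivity over the 8-14 um atmospheric transparency window. Emissivity
#' is derived as 1 - R - T when not supplied.
#'
#' Solar weighting nominally covers 0.28-4.0 um but is capped to the
#' spectrum's own coverage, and must at least span 0.4-2.5 um; thermal
#' weighting covers 2.5-25 um (capped likewise, must span 4-14 um). The
#' bounds actually used are always reported.
#'
#' @param sp A [spectrum()].
#' @param temperature Thermal weighting temperature (K).
#' @param window Atmospheric-window band (um).
#' @param solar_weight_csv Optional CSV (`wavelength_um,weight`) with a
#'   measured solar spectrum; takes precedence over the synthetic weight.
#' @return A `radiometric_summary` list: `solar_reflectance`,
#'   `thermal_emissivity`, `window_emissivity`, `temperature`,
#'   `solar_bounds`, `thermal_bounds`, `window`, `weight_provenance`.
#' @export
radiometric_summary <- function(sp, temperature = 300, window = c(8, 14),
                                solar_weight_csv = NULL) {
  stopifnot(inherits(sp, "spectrum"))
  if (is.null(sp$emissivity)) sp <- emissivity_from_RT(sp)
  wl <- sp$wavelength

  solar_bounds <- c(max(0.28, min(wl)), min(4.0, max(wl)))
  if (solar_bounds[1] > 0.4 + 1e-9 || solar_bounds[2] < 2.5 - 1e-9) {
    stop_silk(sprintf(
      "spectrum [%.3g, %.3g] um cannot support solar weighting (need at least 0.4-2.5 um)",
      min(wl), max(wl)), "silkphotonics_coverage_error")
  }
  thermal_bounds <- c(max(2.5, min(wl)), min(25, max(wl)))
  if (thermal_bounds[1] > 4 + 1e-9 || thermal_bounds[2] < 14 - 1e-9) {
    stop_silk(sprintf(
      "spectrum [%.3g, %.3g] um cannot support thermal weighting (need at least 4-14 um)",
      min(wl), max(wl)), "silkphotonics_coverage_error")
  }

  if (!is.null(solar_weight_csv)) {
    df <- utils::read.csv(solar_weight_csv)
    ws <- list(wavelength = df$wavelength_um, weight = df$weight)
    provenance <- "user"
  } else {
    ws <- NULL
    provenance <- "synthetic"
  }

  solar_r <- weighted_scalar(wl, sp$reflectance, "solar",
                             bounds = solar_bounds, weight_spectrum = ws)
  thermal_e <- weighted_scalar(wl, sp$emissivity, "planck",
                               temperature = temperature,
                               bounds = thermal_bounds)
  window_e <- weighted_scalar(wl, sp$emissivity, "planck",
                              temperature = temperature, bounds = window)

  structure(list(solar_reflectance = solar_r,
                 thermal_emissivity = thermal_e,
                 window_emissivity = window_e,
                 temperature = temperature,
                 solar_bounds = solar_bounds,
                 thermal_bounds = thermal_bounds,
                 window = window,
                 weight_provenance = provenance),
            class = "radiometric_summary")
}

#' @export
print.radiometric_summary <- function(x, ...) {
  cat("<radiometric_summary>\n")
  cat(sprintf("  solar reflectance   %.4f  (%.3g-%.3g um, %s weight)\n",
              x$solar_reflectance, x$solar_bounds[1], x$solar_bounds[2],
              x$weight_provenance))
  cat(sprintf("  thermal emissivity  %.4f  (%.3g-%.3g um, %g K)\n",
              x$thermal_emissivity, x$thermal_bounds[1], x$thermal_bounds[2],
              x$temperature))
  cat(sprintf("  window emissivity   %.4f  (%g-%g um)\n",
              x$window_emissivity, x$window[1], x$window[2]))
  invisible(x)
}
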