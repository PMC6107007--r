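# End-to-end orchestration: run configurations (YAML-serializable nested
# lists), the generator -> propagation -> localization chain, the
# radiometry summary runner, and canonical fixture generation. Every output
# directory receives a machine-readable manifest listing the config hash,
# seeds and file checksums, so reruns are verifiably bit-identical.

#' Default run configuration
#'
#' Nested per-stage parameter list. The defaults describe a modest
#' desk-scale localization experiment: a comet-moth-like disorder density
#' of 2.2 voids/um^2 in a 6-um-radius fiber, a 2-um entrance beam at
#' 600 nm, and a 100-um propagation over 3 disorder realizations.
#'
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    fibergen = list(density = 2.2, size_range = c(0.10, 0.25),
                    fiber_radius = 6, radial_sorting = TRUE),
    bpm = list(omega_0 = 2, wavelength = 0.6, step_dz = 0.25,
               grid_spacing = NULL, total_length = 100,
               n_matrix = 1.54, n_void = 1.0),
    localization = list(n_seeds = 3, lengths = c(50, 100),
                        averaging = "azimuthal"),
    radiometry = list(temperature = 300, window = c(8, 14)),
    tof = list(irf_fwhm = 100, dt = 2, t_range = c(-500, 2000), snr = 50),
    verbosity = 1
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"))
}

log_stage <- function(config, stage, msg) {
  if ((config$verbosity %||% 1) > 0) {
    message(sprintf("[%s] %s", stage, msg))
  }
}

#' Run the localization experiment chain
#'
#' Executes generator -> propagation -> profile averaging -> tail fit for
#' the configured ensemble, writes the localization-length table, the
#' ensemble-averaged profile, an exit-facet preview and a manifest into
#' `outdir`, and returns the table invisibly alongside the fit records.
#'
#' @param config A [default_config()]-style `run_config`.
#' @param outdir Output directory (created if needed).
#' @return List with `xi_table` (data frame), `profiles`, `manifest`.
#' @export
run_localization_experiment <- function(config = default_config(),
                                        outdir = tempfile("silk_loc_")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fg <- config$fibergen; bp <- config$bpm; lc <- config$localization
  h <- bp$grid_spacing %||% (bp$wavelength / (4 * bp$n_matrix))

  log_stage(config, "localize", sprintf(
    "ensemble of %d seeds, L = {%s} um, lambda = %g um",
    lc$n_seeds, paste(lc$lengths, collapse = ", "), bp$wavelength))

  tab <- xi_sweep(
    disorder = fg,
    lengths = lc$lengths, wavelengths = bp$wavelength,
    n_seeds = lc$n_seeds, omega_0 = bp$omega_0,
    step_dz = bp$step_dz, grid_spacing = h, seed = config$seed,
    n_matrix = bp$n_matrix + 0i, n_void = bp$n_void + 0i)

  # one representative exit image + profile at the largest length
  pop <- sample_void_population(
    density = fg$density, size_range = fg$size_range,
    fiber_radius = fg$fiber_radius, radial_sorting = fg$radial_sorting,
    seed = derive_seed(config$seed, 1L))
  cs <- rasterize_cross_section(pop, h, n_matrix = bp$n_matrix + 0i,
                                n_void = bp$n_void + 0i)
  beam <- make_gaussian_beam(bp$omega_0, c(0, 0), bp$wavelength, cs)
  res <- propagate(beam, cs, propagation_config(
    step_dz = bp$step_dz, total_length = max(lc$lengths)))
  img <- intensity_image(res$field)
  prof <- average_log_profile(list(img), lc$averaging)

  files <- list(
    xi_table = file.path(outdir, "xi_table.csv"),
    profile = file.path(outdir, "profile.csv"),
    exit_facet = file.path(outdir, "exit_facet.pgm"),
    config = file.path(outdir, "config.yaml")
  )
  utils::write.csv(tab, files$xi_table, row.names = FALSE, quote = FALSE)
  write_profile_csv(prof, files$profile)
  write_pgm(log1p(unclass(img) / max(img)), files$exit_facet)
  write_run_config(config, files$config)

  manifest <- write_manifest(outdir, files, config)
  invisible(list(xi_table = tab, profiles = list(prof), manifest = manifest,
                 outdir = outdir))
}

#' Run the radiometry summary for a spectrum CSV
#'
#' Reads `wavelength_um,reflectance,transmittance[,emissivity]`, derives
#' emissivity when absent, and writes the scalar summary as JSON.
#'
#' @param spectrum_csv Path to a spectrum CSV.
#' @param config A `run_config` (radiometry section used).
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param solar_weight_csv Optional measured solar spectrum CSV.
#' @return The `radiometric_summary`.
#' @export
run_radiometry <- function(spectrum_csv, config = default_config(),
                           outdir = NULL, solar_weight_csv = NULL) {
  sp <- read_spectrum_csv(spectrum_csv)
  rs <- radiometric_summary(
    sp, temperature = config$radiometry$temperature,
    window = config$radiometry$window,
    solar_weight_csv = solar_weight_csv)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out <- file.path(outdir, "radiometric_summary.json")
    jsonlite::write_json(unclass(rs), out, auto_unbox = TRUE, digits = NA)
    write_manifest(outdir, list(summary = out), config)
  }
  rs
}

#' Generate the canonical test fixtures
#'
#' Writes, under `outdir`: a comet-moth-like 2.2 voids/um^2 void population
#' (JSON), a flat graybody spectrum with emissivity 0.88 (CSV), a synthetic
#' time-of-flight trace with tau = 210 fs plus its IRF (CSV), and an exact
#' exponential intensity profile with xi = 4.6 um (CSV); plus a manifest
#' with per-file checksums. Identical seeds give bit-identical files.
#'
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(seed = 1L, outdir = tempfile("silk_fix_")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()

  pop <- sample_void_population(density = 2.2, size_range = c(0.10, 0.25),
                                fiber_radius = 6, seed = seed)
  files$population <- file.path(outdir, "void_population.json")
  write_population_json(pop, files$population)

  wl <- c(seq(0.3, 2.5, by = 0.05), seq(2.6, 25, by = 0.2))
  sp <- optical_spectrum(wl, rep(0.12, length(wl)), rep(0, length(wl)))
  files$graybody <- file.path(outdir, "graybody_spectrum.csv")
  write_spectrum_csv(sp, files$graybody)

  irf <- gaussian_irf(100, c(-500, 2000), 2)
  trace <- synth_trace(100, 210, c(-500, 2000), 2, snr = 50, seed = seed)
  files$irf <- file.path(outdir, "irf.csv")
  files$trace <- file.path(outdir, "trace_tau210.csv")
  write_trace_csv(irf, files$irf)
  write_trace_csv(trace, files$trace)

  r <- seq(0, 30, by = 0.1)
  prof <- structure(list(r = r, I = exp(-2 * r / 4.6),
                         averaging = "azimuthal", n_realizations = 1L),
                    class = "intensity_profile")
  files$profile <- file.path(outdir, "profile_xi4.6.csv")
  write_profile_csv(prof, files$profile)

  manifest <- write_manifest(outdir, files,
                             list(seed = as.integer(seed),
                                  generator = "make_fixtures"))
  invisible(manifest)
}

write_manifest <- function(outdir, files, config) {
  checksums <- lapply(files, function(f) {
    fnv1a_hash(paste(readLines(f, warn = FALSE), collapse = "\n"))
  })
  manifest <- list(
    package = "silkphotonics",
    version = as.character(utils::packageVersion("silkphotonics")),
    config_hash = config_hash(config),
    seed = config$seed %||% NA_integer_,
    files = mapply(function(f, h) list(path = basename(f), checksum = h),
                   files, checksums, SIMPLIFY = FALSE)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
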