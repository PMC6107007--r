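# Plain-text export helpers: PGM previews, profile/table CSVs, and
# JSON serialization of void populations and cross-section metadata.

#' Write a matrix as a plain (P2) PGM grayscale image
#'
#' Values are rescaled to 0..maxval. Useful for previewing index maps and
#' exit-facet intensities without binary dependencies.
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @param maxval Maximum gray level.
#' @export
write_pgm <- function(mat, path, maxval = 255) {
  m <- as.matrix(mat)
  rng <- range(m)
  g <- if (diff(rng) > 0) round((m - rng[1]) / diff(rng) * maxval)
       else matrix(0, nrow(m), ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(g), nrow(g)),
               sprintf("%d", maxval)), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an intensity profile as two-column CSV (r_um, intensity)
#' @param profile An `intensity_profile`.
#' @param path Output path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(r_um = profile$r, intensity = profile$I),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intensity profile written by [write_profile_csv()]
#' @param path CSV path.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(r = df$r_um, I = df$intensity, averaging = "azimuthal",
                 n_realizations = 1L), class = "intensity_profile")
}

#' Serialize a void population to JSON
#' @param population A `void_population`.
#' @param path Output path.
#' @export
write_population_json <- function(population, path) {
  jsonlite::write_json(list(
    fiber_radius = population$fiber_radius,
    density = population$density,
    realized_density = population$realized_density,
    size_range = population$size_range,
    radial_sorting = population$radial_sorting,
    seed = population$seed,
    voids = population$voids
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a void population from JSON
#' @param path JSON path.
#' @export
read_population_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  voids <- as.data.frame(j$voids)
  if (nrow(voids) == 0) {
    voids <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                        b = numeric(0), orientation = numeric(0),
                        kind = character(0))
  }
  structure(list(voids = voids, fiber_radius = j$fiber_radius,
                 density = j$density,
                 realized_density = j$realized_density,
                 size_range = j$size_range,
                 radial_sorting = j$radial_sorting,
                 seed = as.integer(j$seed)),
            class = "void_population")
}
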