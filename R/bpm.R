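# Scalar split-step (paraxial) beam propagation through a fiber medium.
#
# The field is advanced with the symmetric split-step Fourier scheme: half a
# diffraction step in the spectral domain, a refractive phase screen
# exp(i k0 (n - n_ref) dz) in the real domain, half a diffraction step. A
# super-Gaussian absorbing rim removes power that reaches the grid edge and
# tallies it, so that total power (field + absorbed) is conserved in
# lossless media and conservation is testable.

#' Construct a Gaussian launch beam
#'
#' The amplitude is `exp(-r^2 / omega_0^2)` centered at `center`, normalized
#' to unit total power. `omega_0` is the 1/e radius of the *field* (so the
#' transverse wavenumber entering the localization relation is
#' `k_perp = 2 / omega_0`).
#'
#' @param omega_0 1/e field radius at the entrance facet (um). The entrance
#'   beam used throughout the localization analysis is about 2 um.
#' @param center Beam center `c(x, y)` in um.
#' @param wavelength Vacuum wavelength (um).
#' @param grid A `fiber_cross_section`, or a list with elements `x`, `y`
#'   (pixel-center coordinates, um) and `grid_spacing`.
#' @return An `optical_field` at z = 0 with unit power.
#' @export
make_gaussian_beam <- function(omega_0, center = c(0, 0), wavelength, grid) {
  g <- as_grid(grid)
  if (omega_0 < 2 * g$grid_spacing) {
    stop("omega_0 must be at least 2 grid spacings", call. = FALSE)
  }
  half_x <- (max(g$x) - min(g$x)) / 2
  half_y <- (max(g$y) - min(g$y)) / 2
  if (abs(center[1]) + omega_0 > half_x || abs(center[2]) + omega_0 > half_y) {
    stop("beam wider than grid: enlarge the grid or shrink omega_0",
         call. = FALSE)
  }
  r2 <- outer((g$x - center[1])^2, (g$y - center[2])^2, "+")
  amp <- exp(-r2 / omega_0^2)
  amp <- amp / sqrt(sum(amp^2) * g$grid_spacing^2)
  new_optical_field(amp + 0i, wavelength, g$grid_spacing, z = 0,
                    x = g$x, y = g$y)
}

as_grid <- function(grid) {
  if (inherits(grid, "fiber_cross_section")) {
    list(x = grid$x, y = grid$y, grid_spacing = grid$grid_spacing)
  } else {
    stopifnot(is.list(grid), !is.null(grid$x), !is.null(grid$y),
              !is.null(grid$grid_spacing))
    grid
  }
}

new_optical_field <- function(amplitude, wavelength, grid_spacing, z, x, y) {
  structure(list(amplitude = amplitude, wavelength = wavelength,
                 grid_spacing = grid_spacing, z = z, x = x, y = y),
            class = "optical_field")
}

#' Total power carried by a field
#' @param field An `optical_field`.
#' @return `sum(|amplitude|^2) * spacing^2`.
#' @export
field_power <- function(field) {
  sum(Mod(field$amplitude)^2) * field$grid_spacing^2
}

#' @export
print.optical_field <- function(x, ...) {
  cat(sprintf(
    "<optical_field> %dx%d grid, lambda %.4g um, z = %.4g um, power %.4g\n",
    nrow(x$amplitude), ncol(x$amplitude), x$wavelength, x$z, field_power(x)))
  invisible(x)
}

#' Propagation configuration
#'
#' @param step_dz Axial step (um). Must satisfy the phase-screen sampling
#'   rule `step_dz <= lambda / (2 max|n - n_ref|)`, checked at propagation.
#' @param total_length Propagation distance L (um).
#' @param boundary_width Width of the absorbing rim (um); at least 5 lambda.
#'   `NULL` selects `5 * lambda` at propagation time.
#' @param reference_index Background index of the split-step scheme;
#'   defaults to the matrix index of the medium (minimizing the phase-screen
#'   magnitude inside the fiber).
#' @param snapshot_every Record a summary (and optionally the intensity)
#'   every this many um; `NULL` disables periodic snapshots.
#' @param snapshot_at Explicit z positions (um) at which to record snapshots.
#' @param record `"summary"` records power and mean-square width only;
#'   `"intensity"` additionally stores the intensity image at each snapshot;
#'   `"field"` stores the complex amplitude instead (so the exit-facet
#'   imaging aperture of [na_filter()] can be applied afterwards).
#' @export
propagation_config <- function(step_dz = 0.1, total_length,
                               boundary_width = NULL,
                               reference_index = NULL,
                               snapshot_every = NULL,
                               snapshot_at = NULL,
                               record = c("summary", "intensity", "field")) {
  record <- match.arg(record)
  stopifnot(step_dz > 0, total_length >= 0)
  structure(list(step_dz = step_dz, total_length = total_length,
                 boundary_width = boundary_width,
                 reference_index = reference_index,
                 snapshot_every = snapshot_every,
                 snapshot_at = snapshot_at, record = record),
            class = "propagation_config")
}

#' Propagate a field through a fiber medium
#'
#' Carries `field` over `config$total_length` through `medium` (a
#' `fiber_medium` from [longitudinal_index_sequence()], or a single
#' `fiber_cross_section`, treated as longitudinally invariant). In a uniform
#' medium the scheme reduces to paraxial free-space diffraction and matches
#' the closed-form Gaussian-beam solution; in transversely disordered,
#' longitudinally invariant media the beam first broadens diffusively and
#' then saturates at the transverse localization radius.
#'
#' @param field An `optical_field` on the same grid as the medium.
#' @param medium `fiber_medium` or `fiber_cross_section`.
#' @param config A [propagation_config()].
#' @return A list with `field` (exit field at z = L), `snapshots` (data frame
#'   of z, power, msw — mean-square width about the centroid), `images`
#'   (list of intensity images when `record = "intensity"`),
#'   `absorbed_power`, and `config`.
#' @export
propagate <- function(field, medium, config) {
  stopifnot(inherits(field, "optical_field"),
            inherits(config, "propagation_config"))
  if (inherits(medium, "fiber_cross_section")) {
    medium <- structure(list(planes = list(medium), z = 0, mode = "invariant"),
                        class = "fiber_medium")
  }
  stopifnot(inherits(medium, "fiber_medium"))

  cs1 <- medium$planes[[1]]
  n <- nrow(cs1$index_map)
  if (n != nrow(field$amplitude) ||
      !isTRUE(all.equal(cs1$grid_spacing, field$grid_spacing))) {
    stop("field and medium grids do not match", call. = FALSE)
  }

  lambda <- field$wavelength
  h <- field$grid_spacing
  n_ref <- config$reference_index %||% Re(cs1$n_matrix)
  k0 <- 2 * pi / lambda

  # sampling rules
  max_dn <- max(vapply(medium$planes,
                       function(p) max(Mod(p$index_map - n_ref)), 0))
  if (max_dn > 0) {
    dz_max <- lambda / (2 * max_dn)
    if (config$step_dz > dz_max) {
      stop_silk(sprintf(
        "step_dz = %.4g um violates the phase-screen sampling rule: need step_dz <= lambda/(2 max|n - n_ref|) = %.4g um",
        config$step_dz, dz_max), "silkphotonics_sampling_error")
    }
  }
  max_n <- max(vapply(medium$planes, function(p) max(Re(p$index_map)), 0))
  if (h > lambda / (4 * max_n) * (1 + 1e-9)) {
    stop_silk(sprintf(
      "grid_spacing = %.4g um violates the transverse sampling rule: need spacing <= lambda/(4 max n) = %.4g um",
      h, lambda / (4 * max_n)), "silkphotonics_sampling_error")
  }

  dz <- config$step_dz
  n_steps <- ceiling(config$total_length / dz - 1e-9)
  if (n_steps == 0) {
    return(list(field = field, snapshots = snapshot_row(field, 0),
                images = list(), absorbed_power = 0, config = config))
  }
  dz_last <- config$total_length - (n_steps - 1) * dz

  # spectral kinetic factors (fftfreq convention)
  kx <- 2 * pi * fft_freqs(n, h)
  k2 <- outer(kx^2, kx^2, "+")
  kin <- function(step) exp(-1i * k2 * step / (2 * k0 * n_ref))
  kin_half <- kin(dz / 2)
  kin_last_half <- if (abs(dz_last - dz) > 1e-12) kin(dz_last / 2) else kin_half

  # absorbing rim
  bw <- config$boundary_width %||% (5 * lambda)
  if (bw > 0 && bw < 5 * lambda) bw <- 5 * lambda
  mask <- if (bw > 0) absorber_mask(field$x, field$y, bw) else NULL

  # phase screens, cached per plane
  screens <- new.env(parent = emptyenv())
  screen_for <- function(i, step) {
    key <- sprintf("%d_%.9g", i, step)
    s <- screens[[key]]
    if (is.null(s)) {
      s <- exp(1i * k0 * (medium$planes[[i]]$index_map - n_ref) * step)
      screens[[key]] <- s
    }
    s
  }

  snap_z <- config$snapshot_at
  if (!is.null(config$snapshot_every)) {
    snap_z <- sort(unique(c(snap_z,
      seq(config$snapshot_every, config$total_length, by = config$snapshot_every))))
  }
  snap_z <- snap_z[snap_z > 0 & snap_z <= config$total_length + 1e-9]
  want_images <- config$record %in% c("intensity", "field")
  want_fields <- config$record == "field"

  A <- field$amplitude
  h2 <- h^2
  npix <- length(A)
  absorbed <- 0
  snaps <- list(snapshot_row_amp(A, h, field$x, field$y, 0))
  images <- list()
  z <- 0
  next_snap <- 1L

  # per step: half kinetic (spectral), phase screen + absorber (real),
  # half kinetic (spectral) -- 2 FFTs per step. Consecutive spectral half
  # steps multiply without extra transforms.
  A <- fft(A)
  for (s in seq_len(n_steps)) {
    step <- if (s == n_steps) dz_last else dz
    khalf <- if (s == n_steps) kin_last_half else kin_half
    A <- A * khalf
    A <- fft(A, inverse = TRUE) / npix
    pl <- plane_at(medium, z + step / 2)
    A <- A * screen_for(pl, step)
    if (!is.null(mask)) {
      p_before <- sum(Mod(A)^2)
      A <- A * mask
      absorbed <- absorbed + (p_before - sum(Mod(A)^2)) * h2
    }
    z <- z + step
    A <- fft(A)
    A <- A * khalf
    if (next_snap <= length(snap_z) && z >= snap_z[next_snap] - 1e-9) {
      Areal <- fft(A, inverse = TRUE) / npix
      snaps[[length(snaps) + 1L]] <-
        snapshot_row_amp(Areal, h, field$x, field$y, z)
      if (want_images) {
        img <- if (want_fields) Areal else Mod(Areal)^2
        attr(img, "z") <- z
        images[[length(images) + 1L]] <- img
      }
      next_snap <- next_snap + 1L
    }
  }
  A <- fft(A, inverse = TRUE) / npix

  exit_field <- new_optical_field(A, lambda, h, z, field$x, field$y)
  list(field = exit_field,
       snapshots = do.call(rbind, snaps),
       images = images,
       absorbed_power = absorbed,
       config = config)
}

fft_freqs <- function(n, spacing) {
  f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * spacing)
  f
}

absorber_mask <- function(x, y, bw) {
  ramp <- function(v) {
    half <- max(abs(v))
    d <- pmax(0, (abs(v) - (half - bw)) / bw)
    exp(-8 * d^6)
  }
  outer(ramp(x), ramp(y))
}

snapshot_row_amp <- function(A, h, x, y, z) {
  I <- Mod(A)^2
  p <- sum(I) * h^2
  if (p > 0) {
    wx <- rowSums(I); wy <- colSums(I)
    cx <- sum(wx * x) / sum(wx); cy <- sum(wy * y) / sum(wy)
    msw <- (sum(wx * (x - cx)^2) + sum(wy * (y - cy)^2)) / sum(I)
  } else {
    msw <- NA_real_
  }
  data.frame(z = z, power = p, msw = msw)
}

snapshot_row <- function(field, z) {
  snapshot_row_amp(field$amplitude, field$grid_spacing, field$x, field$y, z)
}

#' Exit-facet intensity image
#'
#' @param field An `optical_field`.
#' @return An `intensity_image`: matrix `|amplitude|^2` with coordinate
#'   attributes `x`, `y`, `grid_spacing`.
#' @export
intensity_image <- function(field) {
  stopifnot(inherits(field, "optical_field"))
  img <- Mod(field$amplitude)^2
  attr(img, "x") <- field$x
  attr(img, "y") <- field$y
  attr(img, "grid_spacing") <- field$grid_spacing
  class(img) <- c("intensity_image", "matrix")
  img
}

#' Imaging-aperture (numerical-aperture) filter
#'
#' Models the finite collection angle of the objective that images the exit
#' facet: transverse spatial frequencies beyond `k0 * na` (vacuum k0, since
#' collection happens in air beyond the facet) are removed with a smooth
#' super-Gaussian edge. The localization measurements this package emulates
#' image the facet through an NA = 0.55 objective, so intensity patterns
#' compared with them should be filtered accordingly.
#'
#' @param field An `optical_field`, or a complex amplitude matrix (then
#'   `wavelength` and `grid_spacing` are required).
#' @param na Numerical aperture of the collection optics.
#' @param wavelength,grid_spacing Needed when `field` is a bare matrix.
#' @return The filtered field (same type as the input).
#' @export
na_filter <- function(field, na = 0.55, wavelength = NULL,
                      grid_spacing = NULL) {
  if (inherits(field, "optical_field")) {
    amp <- field$amplitude
    lam <- field$wavelength
    h <- field$grid_spacing
  } else {
    amp <- field
    lam <- wavelength
    h <- grid_spacing
    stopifnot(!is.null(lam), !is.null(h))
  }
  stopifnot(na > 0)
  n <- nrow(amp)
  kx <- 2 * pi * fft_freqs(n, h)
  kr <- sqrt(outer(kx^2, kx^2, "+"))
  k_max <- 2 * pi / lam * na
  mask <- exp(-(kr / k_max)^16)
  out <- fft(fft(amp) * mask, inverse = TRUE) / length(amp)
  if (inherits(field, "optical_field")) {
    field$amplitude <- out
    field
  } else {
    out
  }
}
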