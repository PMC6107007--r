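# Synthetic fiber cross-sections: random populations of filamentary or
# particulate air voids inside a circular fiber, rasterized to a complex
# refractive-index map for the propagation engine.
#
# Void statistics follow what is seen in SEM cross-sections of nanostructured
# silk fibers: areal densities of a few voids per square micron, void sizes
# from roughly a hundred nanometres to a micron, smaller voids concentrated
# toward the fiber edge and larger ones toward the center, and an optional
# sericin band that is kept free of voids.

#' Sample a random non-overlapping void population
#'
#' Draws a Poisson number of elliptical voids (`density * pi * fiber_radius^2`
#' expected) and places them by dart throwing with strict non-overlap of
#' bounding circles. With `radial_sorting = TRUE` the mean void size ramps
#' linearly from the top of `size_range` at the fiber center down to the
#' bottom of the range at the edge, reproducing the qualitative
#' small-at-the-edge / large-at-the-center arrangement of natural fibers.
#'
#' @param density Target areal void density (voids/um^2). Measured values for
#'   the fibers this generator emulates are 2.2 (comet moth cocoon),
#'   5.5 (regenerated silk) and 17 (PVDF) voids/um^2.
#' @param size_range Length-2 vector, min and max void semi-major axis (um).
#' @param fiber_radius Fiber radius (um).
#' @param radial_sorting Logical; ramp mean void size with radial position.
#' @param eccentricity_range Ellipse eccentricity is drawn uniformly in this
#'   range; the default `c(0, 0.6)` gives mildly irregular voids.
#' @param kind `"filamentary"` (longitudinally invariant) or `"particulate"`.
#' @param seed Integer seed; identical arguments and seed give a
#'   bit-identical population.
#' @param max_attempts Dart-throwing attempts per void before declaring a
#'   packing failure.
#' @param overlap_tolerance Fraction of the bounding-radius sum by which two
#'   voids may encroach; 0 means strict non-overlap.
#' @return A `void_population` object: data frame of void specs plus the
#'   population metadata (fiber radius, requested and realized density, seed).
#' @export
sample_void_population <- function(density,
                                   size_range = c(0.10, 0.25),
                                   fiber_radius = 6,
                                   radial_sorting = TRUE,
                                   eccentricity_range = c(0, 0.6),
                                   kind = c("filamentary", "particulate"),
                                   seed = 1L,
                                   max_attempts = 1e4,
                                   overlap_tolerance = 0) {
  kind <- match.arg(kind)
  stopifnot(density >= 0, fiber_radius > 0,
            length(size_range) == 2, size_range[1] > 0,
            size_range[1] <= size_range[2],
            eccentricity_range[1] >= 0, eccentricity_range[2] < 1)

  smin <- size_range[1]; smax <- size_range[2]
  voids <- with_seed(seed, {
    n_target <- stats::rpois(1L, density * pi * fiber_radius^2)
    if (n_target == 0L) {
      data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                 b = numeric(0), orientation = numeric(0),
                 kind = character(0), stringsAsFactors = FALSE)
    } else {
      place_voids(n_target, density, smin, smax, fiber_radius,
                  radial_sorting, eccentricity_range, kind, max_attempts,
                  overlap_tolerance)
    }
  })

  structure(list(
    voids = voids,
    fiber_radius = fiber_radius,
    density = density,
    realized_density = nrow(voids) / (pi * fiber_radius^2),
    size_range = size_range,
    radial_sorting = radial_sorting,
    seed = as.integer(seed)
  ), class = "void_population")
}

# Dart-throwing placement with a uniform cell grid for neighbor lookup.
# Cell size 2*smax guarantees any overlapping pair lies in adjacent cells.
place_voids <- function(n_target, density, smin, smax, R, radial_sorting,
                        ecc_range, kind, max_attempts, overlap_tolerance) {
  cell <- 2 * smax
  ncell <- max(1L, as.integer(ceiling(2 * R / cell)))
  grid <- vector("list", ncell * ncell)
  cell_of <- function(x, y) {
    i <- pmin(ncell - 1L, pmax(0L, as.integer(floor((x + R) / cell))))
    j <- pmin(ncell - 1L, pmax(0L, as.integer(floor((y + R) / cell))))
    j * ncell + i + 1L
  }

  xs <- ys <- as_ <- bs <- th <- numeric(n_target)
  conc <- 4  # beta concentration for the size draw
  for (k in seq_len(n_target)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      rho <- R * sqrt(stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      x <- rho * cos(phi); y <- rho * sin(phi)
      if (radial_sorting) {
        mu <- 1 - rho / R                    # normalized mean size in [0,1]
        mu <- min(0.9, max(0.1, mu))
        u <- stats::rbeta(1, mu * conc, (1 - mu) * conc)
      } else {
        u <- stats::runif(1)
      }
      a <- smin + (smax - smin) * u
      ecc <- stats::runif(1, ecc_range[1], ecc_range[2])
      b <- a * sqrt(1 - ecc^2)
      # neighbor cells
      ci <- as.integer(floor((x + R) / cell))
      cj <- as.integer(floor((y + R) / cell))
      ok <- TRUE
      for (dj in -1:1) for (di in -1:1) {
        ii <- ci + di; jj <- cj + dj
        if (ii < 0L || jj < 0L || ii >= ncell || jj >= ncell) next
        idx <- grid[[jj * ncell + ii + 1L]]
        if (length(idx)) {
          d2 <- (xs[idx] - x)^2 + (ys[idx] - y)^2
          lim <- ((as_[idx] + a) * (1 - overlap_tolerance))^2
          if (any(d2 <= lim)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        xs[k] <- x; ys[k] <- y; as_[k] <- a; bs[k] <- b
        th[k] <- stats::runif(1, 0, 2 * pi)
        id <- cell_of(x, y)
        grid[[id]] <- c(grid[[id]], k)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      achieved <- (k - 1) / (pi * R^2)
      stop_silk(sprintf(paste0(
        "packing failure: could not place void %d of %d after %d attempts; ",
        "achieved density %.3g voids/um^2 of requested %.3g"),
        k, n_target, max_attempts, achieved, density),
        "silkphotonics_packing_error")
    }
  }
  data.frame(x = xs, y = ys, a = as_, b = bs, orientation = th,
             kind = rep(kind, n_target), stringsAsFactors = FALSE)
}

#' @export
print.void_population <- function(x, ...) {
  cat(sprintf(
    "<void_population> %d voids in fiber of radius %.3g um (seed %d)\n",
    nrow(x$voids), x$fiber_radius, x$seed))
  cat(sprintf("  requested density %.3g, realized %.3g voids/um^2\n",
              x$density, x$realized_density))
  invisible(x)
}

#' Rasterize a void population to a complex refractive-index map
#'
#' Builds a square grid covering the fiber with at least `margin` um of
#' background on every side. A pixel takes `n_void` iff its center lies
#' inside some void ellipse (and inside the fiber disk), `n_matrix` inside
#' the remaining fiber disk, and `n_background` outside. An optional
#' `sericin_band` rectangle (`c(xmin, xmax, ymin, ymax)` um) is forced to
#' `n_matrix`, emulating the void-free sericin region where silk fibers join.
#'
#' @param population A `void_population`.
#' @param grid_spacing Pixel size (um). Must not exceed the smallest void
#'   semi-axis, or voids could be missed entirely.
#' @param n_matrix,n_void,n_background Complex refractive indices. The
#'   defaults are literature-informed values for silk fibroin in the visible
#'   (n = 1.54) and air (n = 1).
#' @param sericin_band Optional rectangle kept void-free, or `NULL`.
#' @param margin Background margin (um) beyond the fiber edge; >= 2.
#' @return A `fiber_cross_section` with the index map, pixel-center
#'   coordinates and construction metadata.
#' @export
rasterize_cross_section <- function(population, grid_spacing,
                                    n_matrix = 1.54 + 0i, n_void = 1 + 0i,
                                    n_background = 1 + 0i,
                                    sericin_band = NULL, margin = 2) {
  stopifnot(inherits(population, "void_population"), grid_spacing > 0,
            margin >= 2)
  v <- population$voids
  if (nrow(v) > 0 && grid_spacing > min(v$b)) {
    stop_silk(sprintf(
      "grid too coarse: spacing %.4g um exceeds smallest void semi-axis %.4g um; use spacing <= %.4g",
      grid_spacing, min(v$b), min(v$b)), "silkphotonics_grid_error")
  }
  R <- population$fiber_radius
  half <- R + margin
  n <- as.integer(ceiling(2 * half / grid_spacing))
  # pixel centers, symmetric about the fiber axis
  coord <- (seq_len(n) - (n + 1) / 2) * grid_spacing
  xm <- matrix(coord, n, n)          # x varies along rows
  ym <- matrix(coord, n, n, byrow = TRUE)
  inside <- xm^2 + ym^2 <= R^2

  map <- matrix(n_background, n, n)
  map[inside] <- n_matrix

  for (k in seq_len(nrow(v))) {
    bound <- v$a[k]
    i0 <- max(1L, findInterval(v$x[k] - bound, coord))
    i1 <- min(n, findInterval(v$x[k] + bound, coord) + 1L)
    j0 <- max(1L, findInterval(v$y[k] - bound, coord))
    j1 <- min(n, findInterval(v$y[k] + bound, coord) + 1L)
    if (i0 > i1 || j0 > j1) next
    dx <- coord[i0:i1] - v$x[k]
    dy <- coord[j0:j1] - v$y[k]
    ct <- cos(v$orientation[k]); st <- sin(v$orientation[k])
    u <- outer(dx, dy, function(p, q) (p * ct + q * st) / v$a[k])
    w <- outer(dx, dy, function(p, q) (-p * st + q * ct) / v$b[k])
    hit <- (u^2 + w^2 <= 1) & inside[i0:i1, j0:j1]
    sub <- map[i0:i1, j0:j1]
    sub[hit] <- n_void
    map[i0:i1, j0:j1] <- sub
  }

  if (!is.null(sericin_band)) {
    stopifnot(length(sericin_band) == 4)
    band <- inside & xm >= sericin_band[1] & xm <= sericin_band[2] &
      ym >= sericin_band[3] & ym <= sericin_band[4]
    map[band] <- n_matrix
  }

  structure(list(
    index_map = map,
    grid_spacing = grid_spacing,
    extent = c(n * grid_spacing, n * grid_spacing),
    x = coord, y = coord,
    population = population,
    n_matrix = n_matrix, n_void = n_void, n_background = n_background,
    sericin_band = sericin_band, margin = margin
  ), class = "fiber_cross_section")
}

#' @export
print.fiber_cross_section <- function(x, ...) {
  cat(sprintf(
    "<fiber_cross_section> %dx%d grid, spacing %.4g um, %d voids\n",
    nrow(x$index_map), ncol(x$index_map), x$grid_spacing,
    nrow(x$population$voids)))
  invisible(x)
}

#' Longitudinal evolution of the disorder
#'
#' Expands one transverse cross-section into a sequence of cross-sections at
#' the given axial positions:
#' * `invariant` — the same map at every z, the filamentary-void idealization
#'   in which voids run unchanged along the fiber;
#' * `morphing` — void centers follow a smooth random walk whose transverse
#'   displacement reaches the mean void size after one `correlation_length`
#'   of propagation, with sizes held fixed (voids slowly wander but persist);
#' * `particulate` — an independent population is resampled at every plane,
#'   emulating fibers whose voids are 3D particles rather than filaments.
#'
#' @param cross_section A `fiber_cross_section` template.
#' @param mode `"invariant"`, `"morphing"` or `"particulate"`.
#' @param correlation_length Axial distance (um) over which a morphing void
#'   center moves by about one mean void size.
#' @param z_positions Increasing axial positions (um) at which planes are
#'   defined; each plane applies from its z up to the next.
#' @param seed Integer seed for the morphing walk / resampling.
#' @return A `fiber_medium`: list of planes plus their z breakpoints.
#' @export
longitudinal_index_sequence <- function(cross_section,
                                        mode = c("invariant", "morphing",
                                                 "particulate"),
                                        correlation_length = 50,
                                        z_positions = 0,
                                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cross_section, "fiber_cross_section"),
            length(z_positions) >= 1, !is.unsorted(z_positions))
  if (mode == "morphing" && correlation_length <= 0) {
    stop("correlation_length must be > 0 for mode = 'morphing'", call. = FALSE)
  }
  pop <- cross_section$population
  ras <- function(p) rasterize_cross_section(
    p, cross_section$grid_spacing, cross_section$n_matrix,
    cross_section$n_void, cross_section$n_background,
    cross_section$sericin_band, cross_section$margin)

  planes <- switch(mode,
    invariant = rep(list(cross_section), length(z_positions)),
    morphing = with_seed(seed, {
      out <- vector("list", length(z_positions))
      out[[1]] <- cross_section
      cur <- pop
      scale <- mean((pop$voids$a + pop$voids$b) / 2)
      if (!is.finite(scale) || nrow(pop$voids) == 0) scale <- 0
      for (i in seq_along(z_positions)[-1]) {
        dz <- z_positions[i] - z_positions[i - 1]
        sd_step <- scale * sqrt(max(dz, 0) / correlation_length)
        nv <- nrow(cur$voids)
        if (nv > 0 && sd_step > 0) {
          cur$voids$x <- cur$voids$x + stats::rnorm(nv, 0, sd_step)
          cur$voids$y <- cur$voids$y + stats::rnorm(nv, 0, sd_step)
          # reflect wanderers back inside the fiber disk
          rr <- sqrt(cur$voids$x^2 + cur$voids$y^2)
          out_of <- rr > cur$fiber_radius
          if (any(out_of)) {
            f <- (2 * cur$fiber_radius - rr[out_of]) / rr[out_of]
            cur$voids$x[out_of] <- cur$voids$x[out_of] * f
            cur$voids$y[out_of] <- cur$voids$y[out_of] * f
          }
        }
        out[[i]] <- ras(cur)
      }
      out
    }),
    particulate = {
      out <- vector("list", length(z_positions))
      for (i in seq_along(z_positions)) {
        p <- sample_void_population(
          density = pop$density, size_range = pop$size_range,
          fiber_radius = pop$fiber_radius,
          radial_sorting = pop$radial_sorting,
          seed = derive_seed(seed, i), kind = "particulate")
        out[[i]] <- ras(p)
      }
      out
    })

  structure(list(planes = planes, z = as.numeric(z_positions), mode = mode,
                 seed = as.integer(seed)),
            class = "fiber_medium")
}

# Plane index active at axial position z (piecewise-constant, last plane
# extends to infinity).
plane_at <- function(medium, z) {
  i <- findInterval(z, medium$z)
  max(1L, min(length(medium$planes), i))
}
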