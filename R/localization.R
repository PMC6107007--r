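# Localization analysis: averaged intensity profiles, exponential-tail fits
# for the localization length xi, inversion of the transverse-localization
# relation for the transport mean free path l*, hotspot FWHM, and the
# ring-pattern image-transport demonstration.
#
# The two working relations are
#   I(r) ~ exp(-2 |r| / xi)                       (exponential tail)
#   xi   = l* exp(pi * k_perp * l*^2 / 2),  k_perp = 2 / omega_0
# so a straight-line fit of ln I against r over the tail gives
# xi = -2 / slope, and l* follows by inverting the strictly increasing map
# l -> l exp(pi k_perp l^2 / 2).

#' Ensemble- and azimuth-averaged intensity profile
#'
#' Intensities are averaged (over realizations, and over azimuth for
#' `averaging = "azimuthal"`) about each image's intensity-weighted
#' centroid; the logarithm is taken downstream by the fitting routine, not
#' here. `"axis-cut"` averages the two half-cuts along the x axis through
#' the centroid instead.
#'
#' @param images A list of 2D intensity matrices on a common grid (e.g.
#'   from [intensity_image()]), or a single matrix.
#' @param averaging `"azimuthal"` or `"axis-cut"`.
#' @param grid_spacing Pixel size (um); taken from the first image's
#'   attribute when present.
#' @return An `intensity_profile` with fields `r`, `I`, `averaging`,
#'   `n_realizations`.
#' @export
average_log_profile <- function(images, averaging = c("azimuthal", "axis-cut"),
                                grid_spacing = NULL) {
  averaging <- match.arg(averaging)
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  h <- grid_spacing %||% attr(images[[1]], "grid_spacing")
  if (is.null(h)) stop("grid_spacing not supplied and not an attribute",
                       call. = FALSE)
  if (all(vapply(images, function(m) all(m == 0), logical(1)))) {
    stop_silk("all images are identically zero", "silkphotonics_input_error")
  }
  n <- nrow(images[[1]])
  x <- attr(images[[1]], "x") %||% ((seq_len(n) - (n + 1) / 2) * h)
  y <- attr(images[[1]], "y") %||% x

  profs <- lapply(images, function(img) {
    wx <- rowSums(img); wy <- colSums(img)
    cx <- sum(wx * x) / sum(wx); cy <- sum(wy * y) / sum(wy)
    if (averaging == "azimuthal") {
      r <- sqrt(outer((x - cx)^2, (y - cy)^2, "+"))
      bin <- pmax(1L, as.integer(round(r / h)) + 1L)
      k <- sort(unique(bin))
      f <- factor(bin, levels = k)
      I <- as.vector(tapply(as.vector(img), f, mean))
      list(r = (k - 1L) * h, I = I)
    } else {
      # nearest row to the centroid's y, folded about the centroid's x
      j <- which.min(abs(y - cy))
      cut <- img[, j]
      rr <- x - cx
      rg <- seq(0, max(abs(rr)) - h, by = h)
      Ip <- stats::approx(rr, cut, xout = rg, rule = 2)$y
      Im <- stats::approx(rr, cut, xout = -rg, rule = 2)$y
      list(r = rg, I = (Ip + Im) / 2)
    }
  })

  r_common <- profs[[1]]$r
  r_max <- min(vapply(profs, function(p) max(p$r), 0))
  r_common <- r_common[r_common <= r_max]
  I_mat <- vapply(profs, function(p)
    stats::approx(p$r, p$I, xout = r_common, rule = 2)$y,
    numeric(length(r_common)))
  I_avg <- if (is.matrix(I_mat)) rowMeans(I_mat) else I_mat

  structure(list(r = r_common, I = I_avg, averaging = averaging,
                 n_realizations = length(images)),
            class = "intensity_profile")
}

#' Fit the localization length from an exponential intensity tail
#'
#' Least-squares straight line on `(r, ln I)` over the fit window; the
#' localization length is `xi = -2 / slope`, with the slope's standard
#' error propagated to xi. A non-negative slope means the profile shows no
#' exponential decay and raises a "not localized" error.
#'
#' @param profile An `intensity_profile`, or any list with `r` and `I`.
#' @param window `c(r_min, r_max)` in um. Default: `r_min` where the profile
#'   first drops to 10% of its peak, `r_max` where it reaches 10x the noise
#'   floor (median of the outermost decile). The window actually used is
#'   always reported in the fit record.
#' @return A `localization_fit` with `xi`, `window`, `slope`,
#'   `slope_stderr`, `xi_stderr`, `r_squared`, `n_points`.
#' @export
fit_localization_length <- function(profile, window = NULL) {
  r <- profile$r; I <- profile$I
  stopifnot(length(r) == length(I), !is.unsorted(r))
  if (is.null(window)) {
    peak <- max(I)
    i_min <- which(I <= 0.1 * peak)
    r_min <- if (length(i_min)) r[min(i_min)] else r[2]
    tail_part <- I[r >= stats::quantile(r, 0.9)]
    floor_est <- stats::median(tail_part[tail_part > 0])
    if (!is.finite(floor_est)) floor_est <- 0
    above <- which(I >= 10 * floor_est)
    r_max <- if (length(above) && max(r[above]) > r_min) max(r[above]) else max(r)
    window <- c(r_min, r_max)
  }
  sel <- r >= window[1] & r <= window[2] & I > 0
  if (sum(sel) < 10) {
    stop_silk(sprintf(
      "fit window [%.3g, %.3g] um contains only %d positive samples (need >= 10)",
      window[1], window[2], sum(sel)), "silkphotonics_fit_error")
  }
  fit <- stats::lm(log(I[sel]) ~ r[sel])
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_silk("profile is not localized: no exponential decay over the fit window",
              "silkphotonics_not_localized_error")
  }
  se <- sm$coefficients[2, 2]
  xi <- -2 / slope
  structure(list(xi = xi, window = window, slope = slope,
                 slope_stderr = se, xi_stderr = 2 * se / slope^2,
                 r_squared = sm$r.squared, n_points = sum(sel)),
            class = "localization_fit")
}

#' @export
print.localization_fit <- function(x, ...) {
  cat(sprintf(
    "<localization_fit> xi = %.4g um (se %.2g), window [%.3g, %.3g] um, R^2 = %.4f\n",
    x$xi, x$xi_stderr, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Invert the localization relation for the transport mean free path
#'
#' Solves `xi = l * exp(pi * k_perp * l^2 / 2)` for `l`, with
#' `k_perp = 2 / omega_0`. The map is strictly increasing from 0 to
#' infinity, so the root is unique; it is found by bracketed bisection to
#' 1e-9 relative accuracy. For the measured values xi = 4.6 um and entrance
#' beam radius omega_0 = 2 um this gives l* of about 0.99 um.
#'
#' @param xi Localization length (um), > 0.
#' @param omega_0 1/e field radius of the entrance beam (um), > 0.
#' @return A `transport_estimate` with `l_star`, `k_perp`, `omega_0`, `xi`.
#' @export
invert_mean_free_path <- function(xi, omega_0) {
  stopifnot(xi > 0, omega_0 > 0)
  k_perp <- 2 / omega_0
  fwd <- function(l) l * exp(pi * k_perp * l^2 / 2)
  hi <- 1
  while (fwd(hi) < xi) hi <- hi * 2
  lo <- 0
  # bisection: interval halves until the relative width is below 1e-12
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (fwd(mid) < xi) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-12 * hi) break
  }
  l_star <- (lo + hi) / 2
  structure(list(l_star = l_star, k_perp = k_perp, omega_0 = omega_0,
                 xi = xi), class = "transport_estimate")
}

#' @export
print.transport_estimate <- function(x, ...) {
  cat(sprintf(
    "<transport_estimate> l* = %.4g um (xi = %.4g um, k_perp = %.4g /um)\n",
    x$l_star, x$xi, x$k_perp))
  invisible(x)
}

#' Forward localization relation
#'
#' @param l_star Mean free path (um).
#' @param omega_0 Entrance beam 1/e field radius (um).
#' @return xi (um) from `l* exp(pi k_perp l*^2 / 2)`.
#' @export
localization_length_forward <- function(l_star, omega_0) {
  l_star * exp(pi * (2 / omega_0) * l_star^2 / 2)
}

#' Sweep the fitted localization length over fiber length and wavelength
#'
#' For every wavelength, generates an ensemble of disordered fibers
#' (`n_seeds` realizations of the same disorder statistics), propagates a
#' Gaussian beam to the largest requested length while recording exit
#' images at every requested length, averages the images per (L, lambda)
#' across the ensemble, and fits the localization length from the averaged
#' profile. The per-seed fit spread is reported as `xi_sd`.
#'
#' @param disorder List of arguments for [sample_void_population()]
#'   (`density`, `size_range`, `fiber_radius`, ...).
#' @param lengths Fiber segment lengths L (um), e.g. the measured segments
#'   300, 400, 720 and 1500 um.
#' @param wavelengths Vacuum wavelengths (um).
#' @param n_seeds Ensemble size per condition.
#' @param omega_0 Entrance beam 1/e field radius (um); about 2 um in the
#'   measurements this emulates.
#' @param step_dz Axial step (um).
#' @param grid_spacing Pixel size (um); `NULL` picks `lambda / (4 n_matrix)`
#'   per wavelength.
#' @param seed Master seed; realization seeds are derived from it.
#' @param n_matrix,n_void Refractive indices passed to the rasterizer.
#' @param margin Background margin (um) around the fiber; must exceed the
#'   absorbing-boundary width (5 lambda) so the absorber never clips the
#'   localized tail.
#' @param imaging_na Collection numerical aperture applied to every exit
#'   field before forming the intensity image ([na_filter()]); the
#'   measurements this emulates image the facet through an NA = 0.55
#'   objective. `NULL` disables the filter.
#' @param window Optional fit window passed to [fit_localization_length()].
#' @return Data frame with columns `L_um`, `lambda_um`, `xi_um`,
#'   `xi_stderr`, `r2`, `xi_sd`, `n_seeds`.
#' @export
xi_sweep <- function(disorder, lengths, wavelengths, n_seeds = 8,
                     omega_0 = 2, step_dz = 0.25, grid_spacing = NULL,
                     seed = 1L, n_matrix = 1.54 + 0i, n_void = 1 + 0i,
                     margin = NULL, imaging_na = 0.55, window = NULL) {
  stopifnot(length(lengths) >= 1, length(wavelengths) >= 1)
  lengths <- sort(lengths)
  rows <- list()
  smin_b <- (disorder$size_range %||% c(0.10, 0.25))[1] * 0.8
  for (lam in wavelengths) {
    # respect both the transverse sampling rule and the rasterizer's
    # coarseness bound (smallest possible void semi-axis)
    h <- grid_spacing %||% min(lam / (4 * Re(n_matrix)), smin_b)
    images <- vector("list", length(lengths))
    for (i in seq_along(images)) images[[i]] <- list()
    for (s in seq_len(n_seeds)) {
      pop <- do.call(sample_void_population,
                     c(disorder, list(seed = derive_seed(seed, s))))
      mar <- margin %||% max(2, 5 * lam + 1.5)
      cs <- rasterize_cross_section(pop, h, n_matrix = n_matrix,
                                    n_void = n_void, margin = mar)
      beam <- make_gaussian_beam(omega_0, c(0, 0), lam, cs)
      cfg <- propagation_config(step_dz = step_dz,
                                total_length = max(lengths),
                                snapshot_at = lengths,
                                record = "field")
      res <- tryCatch(propagate(beam, cs, cfg), error = function(e) {
        stop(sprintf("propagation failed at L=%g, lambda=%g, seed %d: %s",
                     max(lengths), lam, s, conditionMessage(e)),
             call. = FALSE)
      })
      zs <- vapply(res$images, function(im) attr(im, "z"), 0)
      for (i in seq_along(lengths)) {
        k <- which.min(abs(zs - lengths[i]))
        amp <- res$images[[k]]
        if (!is.null(imaging_na)) {
          amp <- na_filter(amp, imaging_na, wavelength = lam,
                           grid_spacing = h)
        }
        img <- Mod(amp)^2
        attr(img, "grid_spacing") <- h
        attr(img, "x") <- cs$x; attr(img, "y") <- cs$y
        images[[i]][[s]] <- img
      }
    }
    for (i in seq_along(lengths)) {
      prof <- average_log_profile(images[[i]], "azimuthal")
      fit <- tryCatch(fit_localization_length(prof, window),
                      error = function(e) NULL)
      per_seed <- vapply(images[[i]], function(img) {
        f <- tryCatch(fit_localization_length(
          average_log_profile(list(img), "azimuthal"), window),
          error = function(e) NULL)
        if (is.null(f)) NA_real_ else f$xi
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        L_um = lengths[i], lambda_um = lam,
        xi_um = if (is.null(fit)) NA_real_ else fit$xi,
        xi_stderr = if (is.null(fit)) NA_real_ else fit$xi_stderr,
        r2 = if (is.null(fit)) NA_real_ else fit$r_squared,
        xi_sd = stats::sd(per_seed, na.rm = TRUE),
        n_seeds = n_seeds)
    }
  }
  do.call(rbind, rows)
}

#' Full width at half maximum of a localized hotspot
#'
#' Locates the global intensity maximum (after optional Gaussian
#' smoothing), refines the hotspot center as the intensity-weighted
#' centroid of the pixels above half maximum around the peak, and measures
#' the FWHM of the azimuthally averaged profile about that center by linear
#' interpolation at half maximum.
#'
#' @param image 2D intensity matrix with `grid_spacing` attribute, or pass
#'   `grid_spacing` explicitly.
#' @param grid_spacing Pixel size (um).
#' @param smooth_sigma Gaussian smoothing sigma (um) applied before peak
#'   finding only; 0 disables.
#' @return List with `fwhm` (um) and `center` (`c(x, y)` um).
#' @export
hotspot_fwhm <- function(image, grid_spacing = NULL, smooth_sigma = 0) {
  h <- grid_spacing %||% attr(image, "grid_spacing")
  if (is.null(h)) stop("grid_spacing required", call. = FALSE)
  n <- nrow(image); m <- ncol(image)
  x <- attr(image, "x") %||% ((seq_len(n) - (n + 1) / 2) * h)
  y <- attr(image, "y") %||% ((seq_len(m) - (m + 1) / 2) * h)
  img <- unclass(image)
  sm <- if (smooth_sigma > 0) gaussian_blur(img, smooth_sigma / h) else img

  peak <- max(sm)
  hits <- which(sm == peak)
  if (length(hits) > 1) {
    ij <- arrayInd(hits, dim(sm))
    if (max(dist(ij)) > 1.5) {
      stop_silk("plateau maximum: hotspot center is ambiguous",
                "silkphotonics_ambiguity_error")
    }
  }
  ij <- arrayInd(hits[1], dim(sm))
  # centroid of the above-half-max pixels within a local window
  w <- 5L
  i_rng <- max(1, ij[1] - w):min(n, ij[1] + w)
  j_rng <- max(1, ij[2] - w):min(m, ij[2] + w)
  loc <- img[i_rng, j_rng]
  mask <- loc >= max(loc) / 2
  wts <- loc * mask
  cx <- sum(outer(x[i_rng], rep(1, length(j_rng))) * wts) / sum(wts)
  cy <- sum(outer(rep(1, length(i_rng)), y[j_rng]) * wts) / sum(wts)

  r <- sqrt(outer((x - cx)^2, (y - cy)^2, "+"))
  bin <- as.integer(round(r / h))
  k <- sort(unique(bin))
  prof <- as.vector(tapply(as.vector(img), factor(bin, levels = k), mean))
  rr <- k * h
  p0 <- prof[1]
  below <- which(prof < p0 / 2)
  if (!length(below)) {
    stop_silk("profile never falls below half maximum within the image",
              "silkphotonics_fit_error")
  }
  k <- min(below)
  # linear interpolation between the bracketing samples
  r_half <- rr[k - 1] + (rr[k] - rr[k - 1]) *
    (p0 / 2 - prof[k - 1]) / (prof[k] - prof[k - 1])
  list(fwhm = 2 * r_half, center = c(cx, cy))
}

# separable Gaussian blur with sigma in pixels
gaussian_blur <- function(img, sigma_px) {
  half <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {
    nv <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[nv], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + nv)]
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(t(tmp), 2, pad_conv))
}

#' Transport of a ring of apertures through a disordered fiber
#'
#' Builds an illumination mask of `n_apertures` circular apertures arranged
#' on a ring, propagates it through the fiber, and scores how well the ring
#' pattern survives: the contrast score is
#' `(mean intensity in the ring annulus - mean elsewhere in the fiber) /
#' (their sum)`, in [-1, 1]. The demonstration geometry uses 1-um apertures
#' on a 30-um-diameter ring through a 400-um fiber segment at 600 nm.
#'
#' @param aperture_diameter Aperture diameter (um).
#' @param ring_diameter Ring diameter (um); must fit inside the fiber.
#' @param n_apertures Number of apertures on the ring.
#' @param medium A `fiber_medium` or `fiber_cross_section`.
#' @param L Fiber length (um); 0 returns the mask itself.
#' @param wavelength Vacuum wavelength (um).
#' @param step_dz Axial step (um).
#' @param annulus_width Width of the scoring annulus (um); default twice the
#'   aperture diameter.
#' @param imaging_na Collection numerical aperture applied to the exit
#'   field before scoring (`NULL` disables); see [na_filter()].
#' @return List with `image` (exit intensity), `contrast`, `mask`.
#' @export
transport_ring_image <- function(aperture_diameter, ring_diameter,
                                 n_apertures, medium, L, wavelength,
                                 step_dz = 0.5, annulus_width = NULL,
                                 imaging_na = 0.55) {
  if (inherits(medium, "fiber_cross_section")) {
    medium <- structure(list(planes = list(medium), z = 0, mode = "invariant"),
                        class = "fiber_medium")
  }
  cs <- medium$planes[[1]]
  Rf <- cs$population$fiber_radius
  if (ring_diameter / 2 + aperture_diameter / 2 > Rf) {
    stop_silk(sprintf(
      "ring of diameter %.3g um (+ apertures) does not fit inside fiber of radius %.3g um",
      ring_diameter, Rf), "silkphotonics_geometry_error")
  }
  h <- cs$grid_spacing
  x <- cs$x; y <- cs$y
  ang <- 2 * pi * (seq_len(n_apertures) - 1) / n_apertures
  cxs <- ring_diameter / 2 * cos(ang)
  cys <- ring_diameter / 2 * sin(ang)
  mask <- matrix(0, length(x), length(y))
  for (k in seq_len(n_apertures)) {
    d2 <- outer((x - cxs[k])^2, (y - cys[k])^2, "+")
    mask[d2 <= (aperture_diameter / 2)^2] <- 1
  }
  amp <- mask + 0i
  p <- sum(Mod(amp)^2) * h^2
  amp <- amp / sqrt(p)
  field <- new_optical_field(amp, wavelength, h, 0, x, y)

  if (L <= 0) {
    img <- intensity_image(field)
    return(list(image = img, contrast = ring_contrast(img, x, y, Rf,
      ring_diameter / 2, annulus_width %||% (2 * aperture_diameter)),
      mask = mask))
  }
  cfg <- propagation_config(step_dz = step_dz, total_length = L)
  res <- propagate(field, medium, cfg)
  exit_field <- res$field
  if (!is.null(imaging_na)) exit_field <- na_filter(exit_field, imaging_na)
  img <- intensity_image(exit_field)
  list(image = img,
       contrast = ring_contrast(img, x, y, Rf, ring_diameter / 2,
                                annulus_width %||% (2 * aperture_diameter)),
       mask = mask)
}

ring_contrast <- function(img, x, y, fiber_radius, ring_radius, width) {
  r <- sqrt(outer(x^2, y^2, "+"))
  in_ann <- abs(r - ring_radius) <= width / 2
  in_fib <- r <= fiber_radius
  m_ann <- mean(img[in_ann & in_fib])
  m_out <- mean(img[in_fib & !in_ann])
  if (m_ann + m_out == 0) return(0)
  (m_ann - m_out) / (m_ann + m_out)
}
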