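# Exact scattering by an infinite dielectric cylinder at normal incidence.
#
# The filamentary voids running along a nanostructured fiber are modeled as
# infinite circular cylinders embedded in the silk matrix. The Bessel-series
# solution gives the scattering/extinction efficiencies for the two
# polarizations; independent-scattering estimates then convert a void
# population's statistics into a transverse scattering mean free path and a
# TE/TM anisotropy ratio.
#
# Polarization naming follows the convention used for fiber measurements:
# TE has the electric field ALONG the fiber (cylinder) axis, TM has it
# perpendicular. (Textbooks on cylinder scattering often label these the
# opposite way; the mapping is TE here = "case I / E-parallel", TM here =
# "case II / E-perpendicular".)

#' Define an infinite-cylinder scatterer
#'
#' @param radius Cylinder radius (um).
#' @param n_cylinder Complex refractive index of the cylinder (1.0 for an
#'   air void).
#' @param n_host Refractive index of the host medium; must be effectively
#'   lossless (|Im| < 1e-6). Defaults to silk fibroin, 1.54.
#' @param wavelength Vacuum wavelength (um).
#' @return A `cylinder_scatterer` with the size parameter
#'   `x = 2 pi n_host radius / lambda`.
#' @export
cylinder_scatterer <- function(radius, n_cylinder, n_host = 1.54 + 0i,
                               wavelength) {
  stopifnot(radius > 0, wavelength > 0, Re(n_host) > 0)
  if (abs(Im(n_host)) > 1e-6) {
    stop("the host medium must be lossless (|Im(n_host)| < 1e-6)",
         call. = FALSE)
  }
  structure(list(radius = radius, n_cylinder = n_cylinder,
                 n_host = n_host, wavelength = wavelength,
                 size_parameter = 2 * pi * Re(n_host) * radius / wavelength),
            class = "cylinder_scatterer")
}

#' Scattering efficiencies of an infinite cylinder at normal incidence
#'
#' Computes the Bessel-series solution truncated at order
#' `x + 4 x^(1/3) + 2`. For TE (E parallel to the axis) the coefficients are
#' `b_n = (m J_n'(mx) J_n(x) - J_n(mx) J_n'(x)) /
#'        (m J_n'(mx) H_n(x) - J_n(mx) H_n'(x))`,
#' and for TM (E perpendicular)
#' `a_n = (J_n'(mx) J_n(x) - m J_n(mx) J_n'(x)) /
#'        (J_n'(mx) H_n(x) - m J_n(mx) H_n'(x))`,
#' with `m = n_cylinder / n_host`. Efficiencies follow as
#' `Q_sca = (2/x) (|c_0|^2 + 2 sum |c_n|^2)` and
#' `Q_ext = (2/x) Re(c_0 + 2 sum c_n)` (optical theorem).
#'
#' @param scatterer A [cylinder_scatterer()]. Size parameter must be < 200.
#' @param polarization `"TE"` (E along the axis) or `"TM"`.
#' @param n_angles Number of azimuthal samples for the angular pattern.
#' @param extra_orders Additional truncation orders beyond the default rule
#'   (used by convergence tests).
#' @return A `scattering_result` with `Q_sca`, `Q_ext`, `Q_abs`,
#'   `polarization`, `coefficients` and `angular_pattern` (data frame of
#'   `theta`, `intensity`, normalized to unit maximum).
#' @export
cylinder_scattering <- function(scatterer, polarization = c("TE", "TM"),
                                n_angles = 361, extra_orders = 0) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(scatterer, "cylinder_scatterer"))
  x <- scatterer$size_parameter
  if (x >= 200) {
    stop_silk(sprintf(
      "size parameter %.4g exceeds the series truncation bound 200", x),
      "silkphotonics_truncation_error")
  }
  m <- scatterer$n_cylinder / scatterer$n_host
  theta <- seq(0, 2 * pi, length.out = n_angles)

  if (abs(m - 1) == 0) {
    pattern <- data.frame(theta = theta, intensity = rep(0, n_angles))
    return(structure(list(Q_sca = 0, Q_ext = 0, Q_abs = 0,
                          polarization = polarization,
                          coefficients = complex(0),
                          angular_pattern = pattern,
                          scatterer = scatterer),
                     class = "scattering_result"))
  }

  nmax <- as.integer(ceiling(x + 4 * x^(1 / 3) + 2)) + as.integer(extra_orders)
  nn <- 0:nmax
  Jx <- besselJ(x, 0:(nmax + 1))
  Yx <- besselY(x, 0:(nmax + 1))
  Jxp <- c(-Jx[2], Jx[nn[-1]] - nn[-1] / x * Jx[nn[-1] + 1]) # J_n' = J_{n-1} - n/x J_n
  Yxp <- c(-Yx[2], Yx[nn[-1]] - nn[-1] / x * Yx[nn[-1] + 1])
  Jx <- Jx[1:(nmax + 1)]; Yx <- Yx[1:(nmax + 1)]
  Hx <- complex(real = Jx, imaginary = Yx)
  Hxp <- complex(real = Jxp, imaginary = Yxp)

  mx <- m * x
  Jm <- besselJ_complex(mx, nmax)
  Jmp <- c(-Jm[2], Jm[nn[-1]] - nn[-1] / mx * Jm[nn[-1] + 1])
  Jm <- Jm[1:(nmax + 1)]

  if (polarization == "TE") {
    num <- m * Jmp * Jx - Jm * Jxp
    den <- m * Jmp * Hx - Jm * Hxp
  } else {
    num <- Jmp * Jx - m * Jm * Jxp
    den <- Jmp * Hx - m * Jm * Hxp
  }
  cn <- num / den

  Q_sca <- (2 / x) * (Mod(cn[1])^2 + 2 * sum(Mod(cn[-1])^2))
  Q_ext <- (2 / x) * Re(cn[1] + 2 * sum(cn[-1]))
  # scattering amplitude T(theta) = c_0 + 2 sum c_n cos(n theta)
  Tm <- outer(theta, 1:nmax, function(th, n) cos(n * th))
  amp <- cn[1] + 2 * as.vector(Tm %*% cn[-1])
  inten <- Mod(amp)^2
  if (max(inten) > 0) inten <- inten / max(inten)

  structure(list(Q_sca = Q_sca, Q_ext = Q_ext, Q_abs = Q_ext - Q_sca,
                 polarization = polarization, coefficients = cn,
                 angular_pattern = data.frame(theta = theta,
                                              intensity = inten),
                 scatterer = scatterer),
            class = "scattering_result")
}

#' @export
print.scattering_result <- function(x, ...) {
  cat(sprintf(
    "<scattering_result> %s: Q_sca = %.6g, Q_ext = %.6g, Q_abs = %.3g (x = %.4g)\n",
    x$polarization, x$Q_sca, x$Q_ext, x$Q_abs,
    x$scatterer$size_parameter))
  invisible(x)
}

# Bessel J_0..J_nmax at a complex (or real) argument by Miller's downward
# recurrence, normalized with J_0 + 2 sum J_2k = 1. For a real argument the
# base besselJ is used directly.
besselJ_complex <- function(z, nmax) {
  need <- nmax + 1L  # order nmax+1 is needed for derivatives upstream
  if (Im(z) == 0) {
    return(as.complex(besselJ(Re(z), 0:need)))
  }
  az <- Mod(z)
  if (az == 0) {
    return(c(1 + 0i, rep(0 + 0i, need)))
  }
  M <- as.integer(max(need, ceiling(az)) +
                    ceiling(2 * sqrt(max(need, az))) + 35)
  fp <- 0 + 0i            # J_{n+1}
  f <- 1e-280 + 0i        # J_n, starting at n = M
  out <- rep(0 + 0i, need + 1L)
  norm <- if (M %% 2L == 0L) 2 * f else 0 + 0i
  for (n in M:1) {
    fm <- (2 * n / z) * f - fp   # J_{n-1}
    fp <- f
    f <- fm
    nm <- n - 1L
    if (nm <= need) out[nm + 1L] <- f
    if (nm > 0L && nm %% 2L == 0L) norm <- norm + 2 * f
    if (Mod(f) > 1e250) {
      f <- f * 1e-250; fp <- fp * 1e-250
      out <- out * 1e-250; norm <- norm * 1e-250
    }
  }
  norm <- norm + f  # + J_0, completing J_0 + 2 sum_k J_{2k} = 1
  out / norm
}

#' Transverse scattering mean free path under independent scattering
#'
#' `l = 1 / (rho * <sigma>)` with `<sigma>` the size-averaged 2D scattering
#' cross-section per unit cylinder length (efficiency times diameter),
#' averaged over the void size distribution with 64-point Gauss-Legendre
#' quadrature. Independent scattering ignores inter-void correlations, so at
#' the densities found in real fibers this is an order-of-magnitude
#' estimate, not a precision prediction.
#'
#' @param population_stats List with `density` (voids/um^2) and
#'   `size_range` (`c(min, max)` radius, um); optionally `size_weights`, a
#'   function of radius giving an (unnormalized) size density (uniform when
#'   omitted).
#' @param wavelength Vacuum wavelength (um).
#' @param polarization `"TE"` or `"TM"`.
#' @param n_host Host index (silk matrix by default).
#' @param n_cylinder Void index (air by default).
#' @param n_quad Quadrature points over the size range.
#' @return Mean free path (um); `Inf` beyond 1e6 um (the documented
#'   "effectively infinite" sentinel for the dilute limit).
#' @export
independent_mean_free_path <- function(population_stats, wavelength,
                                       polarization = c("TE", "TM"),
                                       n_host = 1.54 + 0i,
                                       n_cylinder = 1 + 0i,
                                       n_quad = 64) {
  polarization <- match.arg(polarization)
  rho <- population_stats$density
  stopifnot(!is.null(rho), rho >= 0)
  if (rho == 0) return(Inf)
  sig <- mean_cross_section(population_stats, wavelength, polarization,
                            n_host, n_cylinder, n_quad)
  l <- 1 / (rho * sig)
  if (l > 1e6) Inf else l
}

mean_cross_section <- function(population_stats, wavelength, polarization,
                               n_host, n_cylinder, n_quad = 64) {
  sr <- population_stats$size_range
  stopifnot(length(sr) == 2, sr[1] > 0, sr[2] >= sr[1])
  wfun <- population_stats$size_weights %||% (function(r) rep(1, length(r)))
  if (sr[1] == sr[2]) {
    q <- cylinder_scattering(
      cylinder_scatterer(sr[1], n_cylinder, n_host, wavelength),
      polarization)
    return(q$Q_sca * 2 * sr[1])
  }
  gl <- pracma::gaussLegendre(n_quad, sr[1], sr[2])
  sig <- vapply(gl$x, function(r) {
    q <- cylinder_scattering(
      cylinder_scatterer(r, n_cylinder, n_host, wavelength), polarization)
    q$Q_sca * 2 * r
  }, 0)
  w <- wfun(gl$x)
  sum(gl$w * w * sig) / sum(gl$w * w)
}

#' TE/TM anisotropy of the mean scattering cross-section
#'
#' Ratio of the size-averaged TE to TM cross-sections for a void
#' population. Values above 1 mean light polarized along the voids
#' scatters more strongly — the form-birefringence ordering seen in
#' polarization-resolved reflectance and time-of-flight measurements on
#' filamentary-void fibers.
#'
#' @inheritParams independent_mean_free_path
#' @return Ratio `<sigma_TE> / <sigma_TM>` (dimensionless).
#' @export
polarization_anisotropy <- function(population_stats, wavelength,
                                    n_host = 1.54 + 0i, n_cylinder = 1 + 0i,
                                    n_quad = 64) {
  if (abs(n_cylinder - n_host) == 0) {
    stop_silk("no index contrast: anisotropy ratio is undefined (0/0)",
              "silkphotonics_input_error")
  }
  s_te <- mean_cross_section(population_stats, wavelength, "TE",
                             n_host, n_cylinder, n_quad)
  s_tm <- mean_cross_section(population_stats, wavelength, "TM",
                             n_host, n_cylinder, n_quad)
  s_te / s_tm
}

#' Rayleigh-limit efficiencies for a thin cylinder
#'
#' Closed-form small-size-parameter limits,
#' `Q_TE = pi^2 x^3 (m^2-1)^2 / 8` and
#' `Q_TM = pi^2 x^3 (m^2-1)^2 / (4 (m^2+1)^2)`, valid for `x << 1`. Used as
#' the independent oracle for the series solution.
#'
#' @param x Size parameter.
#' @param m Relative refractive index `n_cylinder / n_host`.
#' @param polarization `"TE"` or `"TM"`.
#' @return Scattering efficiency in the Rayleigh limit.
#' @export
rayleigh_cylinder_Q <- function(x, m, polarization = c("TE", "TM")) {
  polarization <- match.arg(polarization)
  base <- pi^2 * x^3 * (m^2 - 1)^2
  if (polarization == "TE") base / 8 else base / (4 * (m^2 + 1)^2)
}
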