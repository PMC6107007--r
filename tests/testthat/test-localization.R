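# Localization analysis: profile averaging, tail fitting, the mean-free-path
# inversion, hotspot FWHM, ring contrast.

test_that("a radially symmetric exponential image yields its own profile", {
  xi <- 4.6
  img <- exponential_image(xi)
  prof <- average_log_profile(list(img), "azimuthal")
  sel <- prof$r > 0.5 & prof$r < 8
  expect_lt(max(abs(prof$I[sel] - exp(-2 * prof$r[sel] / xi)) /
                  exp(-2 * prof$r[sel] / xi)), 0.05)

  # axis-cut and azimuthal averaging agree on a symmetric image
  prof2 <- average_log_profile(list(img), "axis-cut")
  common <- intersect(round(prof$r, 6), round(prof2$r, 6))
  common <- common[common < 8]
  i1 <- match(common, round(prof$r, 6)); i2 <- match(common, round(prof2$r, 6))
  expect_lt(max(abs(prof$I[i1] - prof2$I[i2]) / pmax(prof$I[i1], 1e-12)),
            0.01)
})

test_that("averaging N noisy replicates shrinks the variance like 1/N", {
  base <- exponential_image(3, n = 101)
  make_noisy <- function(s) {
    img <- base * matrix(exp(rnorm(length(base), 0, 0.2)),
                         nrow(base), ncol(base))
    attributes(img) <- attributes(base)
    img
  }
  set.seed(99)
  profs_1 <- replicate(30, {
    p <- average_log_profile(list(make_noisy()), "azimuthal")
    p$I[20]
  })
  profs_16 <- replicate(30, {
    p <- average_log_profile(lapply(1:16, make_noisy), "azimuthal")
    p$I[20]
  })
  ratio <- stats::var(profs_1) / stats::var(profs_16)
  expect_gt(ratio, 16 / 3)  # ~16 expected; generous band for 30 reps
  expect_lt(ratio, 16 * 3)
})

test_that("all-zero images are refused", {
  z <- matrix(0, 32, 32)
  attr(z, "grid_spacing") <- 0.1
  expect_error(average_log_profile(list(z)),
               class = "silkphotonics_input_error")
})

test_that("an exact exponential profile fits back to its xi", {
  r <- seq(0, 25, by = 0.05)
  prof <- list(r = r, I = exp(-2 * r / 4.6))
  fit <- fit_localization_length(prof, window = c(1, 20))
  expect_equal(fit$xi, 4.6, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("xi is recovered within 5% from noisy averaged profiles", {
  # multiplicative log-normal noise, 50 realizations averaged per profile
  r <- seq(0, 15, by = 0.05)
  for (xi in c(1, 2, 4.6, 10)) {
    set.seed(1000 + round(10 * xi))
    I_avg <- rowMeans(vapply(1:50, function(k) {
      exp(-2 * r / xi) * exp(rnorm(length(r), 0, 0.1))
    }, numeric(length(r))))
    fit <- fit_localization_length(list(r = r, I = I_avg),
                                   window = c(0.3, min(15, 3 * xi)))
    expect_lt(abs(fit$xi - xi) / xi, 0.05)
  }
})

test_that("flat or growing profiles raise a not-localized error", {
  r <- seq(0, 10, by = 0.1)
  expect_error(
    fit_localization_length(list(r = r, I = rep(1, length(r))),
                            window = c(0, 10)),
    class = "silkphotonics_not_localized_error")
  expect_error(
    fit_localization_length(list(r = r, I = exp(r / 5)), window = c(0, 10)),
    class = "silkphotonics_not_localized_error")
})

test_that("xi estimates are invariant under intensity rescaling", {
  r <- seq(0, 12, by = 0.05)
  set.seed(7)
  I <- exp(-2 * r / 3) * exp(rnorm(length(r), 0, 0.05))
  f1 <- fit_localization_length(list(r = r, I = I), window = c(0.5, 10))
  f2 <- fit_localization_length(list(r = r, I = 1e6 * I),
                                window = c(0.5, 10))
  expect_equal(f1$xi, f2$xi, tolerance = 1e-12)
})

test_that("the mean-free-path inversion reproduces the printed worked example", {
  est <- invert_mean_free_path(4.6, 2)
  expect_gt(est$l_star, 0.97)
  expect_lt(est$l_star, 1.00)
  expect_equal(est$k_perp, 1)
  # forward evaluation reproduces the input xi
  expect_equal(localization_length_forward(est$l_star, 2), 4.6,
               tolerance = 1e-9)
})

test_that("inversion is the exact inverse of the forward relation", {
  # roundtrip identity at a known point
  xi <- localization_length_forward(0.5, 2)
  expect_equal(xi, 0.5 * exp(pi * 0.25 / 2))
  expect_equal(invert_mean_free_path(xi, 2)$l_star, 0.5, tolerance = 1e-9)

  # property: random pairs against a dense-grid scan oracle
  set.seed(31)
  for (k in 1:100) {
    omega_0 <- runif(1, 0.5, 5)
    xi <- runif(1, 0.1, 50)
    est <- invert_mean_free_path(xi, omega_0)
    grid <- seq(1e-4, 10, by = 1e-4)
    fwd <- grid * exp(pi * (2 / omega_0) * grid^2 / 2)
    oracle <- grid[which.min(abs(fwd - xi))]
    expect_lt(abs(est$l_star - oracle), 1e-3)
    expect_equal(localization_length_forward(est$l_star, omega_0), xi,
                 tolerance = 1e-9)
  }
})

test_that("hotspot FWHM matches the Gaussian closed form and is scale-free", {
  sigma <- 0.8
  img <- gaussian_image(sigma, n = 301, h = 0.05)
  res <- hotspot_fwhm(img)
  expect_lt(abs(res$fwhm - 2.3548 * sigma) / (2.3548 * sigma), 0.01)
  expect_lt(max(abs(res$center)), 0.05)

  res2 <- hotspot_fwhm(img * 37.5)
  expect_equal(res2$fwhm, res$fwhm, tolerance = 1e-12)
})

test_that("with two unequal hotspots the taller one is measured", {
  h <- 0.05
  a <- gaussian_image(0.5, n = 301, h = h, center = c(-3, 0), height = 1)
  b <- gaussian_image(0.9, n = 301, h = h, center = c(4, 0), height = 0.4)
  img <- a + b
  attributes(img) <- attributes(a)
  res <- hotspot_fwhm(img)
  expect_lt(abs(res$center[1] - (-3)), 0.1)
  expect_lt(abs(res$fwhm - 2.3548 * 0.5) / (2.3548 * 0.5), 0.05)
})

test_that("a plateau maximum raises an ambiguity error", {
  img <- matrix(0, 51, 51)
  img[10:15, 25] <- 1  # flat-topped ridge
  attr(img, "grid_spacing") <- 0.1
  expect_error(hotspot_fwhm(img), class = "silkphotonics_ambiguity_error")
})

test_that("ring transport at L = 0 returns the mask with maximal contrast", {
  cs <- tiny_cross_section(density = 0, fiber_radius = 17,
                           grid_spacing = 0.09, margin = 3.5)
  res <- transport_ring_image(1, 30, 16, cs, L = 0, wavelength = 0.6)
  expect_equal(unclass(res$image) > 0, res$mask > 0)
  expect_equal(res$contrast, 1)
  expect_lte(res$contrast, 1)
  expect_gte(res$contrast, -1)
})

test_that("rings larger than the fiber are refused", {
  cs <- tiny_cross_section(density = 0, fiber_radius = 10,
                           grid_spacing = 0.09, margin = 3.5)
  expect_error(transport_ring_image(1, 30, 16, cs, L = 0, wavelength = 0.6),
               class = "silkphotonics_geometry_error")
})
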