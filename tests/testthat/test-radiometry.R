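# Radiometry: emissivity arithmetic and clipping, Planck law integrals,
# weighted scalars and their invariances, the synthetic solar weight, and
# CSV round-trips.

test_that("emissivity is 1 - R - T with the documented clipping policy", {
  wl <- seq(0.4, 20, by = 0.1)
  sp <- optical_spectrum(wl, rep(0.3, length(wl)), rep(0.2, length(wl)))
  sp <- emissivity_from_RT(sp)
  expect_equal(sp$emissivity, rep(0.5, length(wl)))

  # perfect mirror: emissivity identically zero
  sp2 <- emissivity_from_RT(optical_spectrum(wl, rep(1, length(wl)),
                                             rep(0, length(wl))))
  expect_true(all(sp2$emissivity == 0))

  # R + T slightly above 1: clipped to 0 with a warning
  refl <- rep(0.3, length(wl)); refl[5] <- 0.8005
  trans <- rep(0.2, length(wl)); trans[5] <- 0.2
  sp3 <- optical_spectrum(wl, refl, trans)
  expect_warning(sp3 <- emissivity_from_RT(sp3), "clipped")
  expect_equal(sp3$emissivity[5], 0)

  # R + T far above 1 is a data-quality error
  refl[5] <- 0.9
  expect_error(emissivity_from_RT(optical_spectrum(wl, refl, trans)),
               class = "silkphotonics_data_error")
})

test_that("spectrum construction validates its grid", {
  expect_error(optical_spectrum(c(1, 1, 2), rep(0.1, 3), rep(0, 3)),
               "strictly increasing")
  expect_error(optical_spectrum(c(1, 2), c(0.5, 1.2), c(0, 0)), "0, 1")
})

test_that("the Planck integral reproduces the Stefan-Boltzmann law", {
  wl <- exp(seq(log(0.1), log(1000), length.out = 20000))
  for (T_K in c(300, 600)) {
    total <- pracma::trapz(wl, planck_spectral_emissive_power(wl, T_K))
    expect_lt(abs(total - 5.670374419e-8 * T_K^4) / (5.670374419e-8 * T_K^4),
              1e-3)
  }
  # T^4 scaling
  t1 <- pracma::trapz(wl, planck_spectral_emissive_power(wl, 300))
  t2 <- pracma::trapz(wl, planck_spectral_emissive_power(wl, 600))
  expect_lt(abs(t2 / t1 - 16) / 16, 0.005)
  # Wien displacement at 300 K
  wl_fine <- seq(5, 20, by = 0.001)
  peak <- wl_fine[which.max(planck_spectral_emissive_power(wl_fine, 300))]
  expect_lt(abs(peak - 2897.77 / 300), 0.01)
})

test_that("weighting a constant returns the constant for any weight", {
  wl <- seq(0.3, 25, by = 0.05)
  for (w in c("planck", "solar")) {
    bounds <- if (w == "solar") c(0.3, 4) else c(2.5, 25)
    val <- weighted_scalar(wl, rep(0.88, length(wl)), w, 300, bounds)
    expect_equal(val, 0.88, tolerance = 1e-9)
  }
})

test_that("the 8-14 um band fraction matches a fine-grid oracle", {
  wl <- seq(2.5, 25, by = 0.001)
  f <- as.numeric(wl >= 8 & wl <= 14)
  val <- weighted_scalar(wl, f, "planck", 300, c(2.5, 25))
  # independent fine-grid quadrature of the blackbody band fraction
  g <- seq(2.5, 25, length.out = 2e5)
  pg <- planck_spectral_emissive_power(g, 300)
  oracle <- pracma::trapz(g[g >= 8 & g <= 14], pg[g >= 8 & g <= 14]) /
    pracma::trapz(g, pg)
  expect_lt(abs(val - oracle), 1e-4)
})

test_that("weighted scalars are linear in the spectral quantity", {
  wl <- seq(2.5, 25, by = 0.05)
  set.seed(4)
  f <- runif(length(wl)); g <- runif(length(wl))
  a <- 0.37; b <- 1.21
  lhs <- weighted_scalar(wl, a * f + b * g, "planck", 300, c(3, 20))
  rhs <- a * weighted_scalar(wl, f, "planck", 300, c(3, 20)) +
    b * weighted_scalar(wl, g, "planck", 300, c(3, 20))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("graybody identity holds for random constants and bounds", {
  set.seed(11)
  wl <- seq(0.3, 25, by = 0.02)
  for (k in 1:10) {
    eps <- runif(1)
    lo <- runif(1, 0.4, 10); hi <- lo + runif(1, 1, 10)
    val <- weighted_scalar(wl, rep(eps, length(wl)), "planck", 300,
                           c(lo, min(hi, 24)))
    expect_equal(val, eps, tolerance = 1e-9)
  }
})

test_that("pointwise-larger emissivity never lowers the weighted value", {
  set.seed(5)
  wl <- seq(2.5, 25, by = 0.05)
  e1 <- runif(length(wl), 0, 0.5)
  e2 <- e1 + runif(length(wl), 0, 0.5)
  v1 <- weighted_scalar(wl, e1, "planck", 300, c(3, 20))
  v2 <- weighted_scalar(wl, e2, "planck", 300, c(3, 20))
  expect_gte(v2, v1)
})

test_that("weighted scalars are stable under grid-density doubling", {
  wl <- seq(2.5, 25, by = 0.04)
  eps <- 0.3 + 0.5 * exp(-((wl - 10) / 3)^2)
  v1 <- weighted_scalar(wl, eps, "planck", 300, c(3, 20))
  wl2 <- seq(2.5, 25, by = 0.02)
  eps2 <- 0.3 + 0.5 * exp(-((wl2 - 10) / 3)^2)
  v2 <- weighted_scalar(wl2, eps2, "planck", 300, c(3, 20))
  expect_lt(abs(v1 - v2), 1e-4)
})

test_that("coverage gaps are refused with the missing range named", {
  wl <- seq(0.4, 2.0, by = 0.01)
  expect_error(
    weighted_scalar(wl, rep(1, length(wl)), "planck", 300, c(0.4, 4)),
    class = "silkphotonics_coverage_error")
})

test_that("the synthetic solar weight is non-negative and normalizable", {
  sw <- synthetic_solar_weight(c(0.28, 4), normalize = TRUE)
  expect_true(all(sw$weight >= 0))
  expect_equal(pracma::trapz(sw$wavelength, sw$weight), 1, tolerance = 1e-9)
  expect_identical(sw$provenance, "synthetic")
})

test_that("a user-supplied solar weight takes precedence over the synthetic one", {
  wl <- seq(0.3, 25, by = 0.02)
  refl <- 0.9 - 0.5 * plogis((wl - 3) / 0.5)  # high solar, low IR reflectance
  sp <- optical_spectrum(wl, refl, rep(0, length(wl)))
  csv <- tempfile(fileext = ".csv")
  # a deliberately red-shifted "measured" weight must change the answer
  utils::write.csv(data.frame(wavelength_um = seq(0.3, 4, by = 0.01),
                              weight = seq(0.3, 4, by = 0.01)^4),
                   csv, row.names = FALSE)
  rs_syn <- radiometric_summary(sp)
  rs_usr <- radiometric_summary(sp, solar_weight_csv = csv)
  expect_identical(rs_syn$weight_provenance, "synthetic")
  expect_identical(rs_usr$weight_provenance, "user")
  expect_false(isTRUE(all.equal(rs_syn$solar_reflectance,
                                rs_usr$solar_reflectance)))
})

test_that("spectra round-trip through CSV", {
  wl <- seq(0.4, 20, by = 0.1)
  sp <- optical_spectrum(wl, runif(length(wl), 0, 0.5),
                         runif(length(wl), 0, 0.3))
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$reflectance, sp$reflectance, tolerance = 1e-12)
  expect_error(read_spectrum_csv(textConnection("a,b\n1,2")))
})
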