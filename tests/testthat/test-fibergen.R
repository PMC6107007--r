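# Void-population generator: determinism, density statistics, radial size
# sorting, rasterization geometry, packing behavior, longitudinal modes.

test_that("zero density gives an empty population and a uniform disk", {
  pop <- sample_void_population(0, fiber_radius = 10, seed = 5)
  expect_equal(nrow(pop$voids), 0L)
  expect_equal(pop$realized_density, 0)

  cs <- rasterize_cross_section(pop, 0.1)
  vals <- unique(as.vector(cs$index_map))
  expect_setequal(vals, c(cs$n_matrix, cs$n_background))
  # disk area check: matrix pixels ~ pi R^2
  n_disk <- sum(cs$index_map == cs$n_matrix)
  expect_lt(abs(n_disk * 0.1^2 - pi * 100) / (pi * 100), 0.01)
})

test_that("identical arguments and seed give bit-identical populations", {
  a <- sample_void_population(2.2, fiber_radius = 8, seed = 17)
  b <- sample_void_population(2.2, fiber_radius = 8, seed = 17)
  expect_identical(a, b)
  c <- sample_void_population(2.2, fiber_radius = 8, seed = 18)
  expect_false(identical(a$voids, c$voids))
})

test_that("void counts follow Poisson statistics at the comet-moth density", {
  R <- 12; dens <- 2.2; n_seeds <- 40
  counts <- vapply(seq_len(n_seeds), function(s) {
    nrow(sample_void_population(dens, fiber_radius = R, seed = s)$voids)
  }, 0L)
  mu <- dens * pi * R^2
  # mean of n_seeds Poisson draws: 3-sigma band of the standard error
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n_seeds))
})

test_that("all voids lie inside the fiber disk and never overlap", {
  pop <- sample_void_population(2.2, fiber_radius = 10, seed = 3)
  v <- pop$voids
  expect_true(all(sqrt(v$x^2 + v$y^2) <= pop$fiber_radius))
  d <- as.matrix(dist(cbind(v$x, v$y)))
  lim <- outer(v$a, v$a, "+")
  diag(d) <- Inf
  expect_true(all(d > lim | !is.finite(d)))
})

test_that("radial sorting makes void size decrease with radial position", {
  n_neg <- 0; n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    pop <- sample_void_population(2.2, fiber_radius = 8, seed = s,
                                  radial_sorting = TRUE)
    v <- pop$voids
    rho <- sqrt(v$x^2 + v$y^2)
    if (stats::cor(rho, v$a, method = "spearman") < 0) n_neg <- n_neg + 1
  }
  expect_gte(n_neg, 48)
})

test_that("realized density converges to the requested density", {
  # spatial-average check on large fibers
  dens <- 2.2; R <- 50
  rel <- vapply(1:20, function(s) {
    p <- sample_void_population(dens, fiber_radius = R, seed = s)
    p$realized_density / dens - 1
  }, 0)
  expect_lt(abs(mean(rel)), 0.02)
})

test_that("infeasible packing raises an explicit packing error", {
  expect_error(
    sample_void_population(30, size_range = c(0.3, 0.5), fiber_radius = 6,
                           seed = 1, max_attempts = 200),
    class = "silkphotonics_packing_error")
  expect_error(
    sample_void_population(30, size_range = c(0.3, 0.5), fiber_radius = 6,
                           seed = 1, max_attempts = 200),
    "achieved density")
})

test_that("a single circular void rasterizes to the analytic area", {
  pop <- sample_void_population(0, fiber_radius = 5, seed = 1)
  pop$voids <- data.frame(x = 0.6, y = -0.4, a = 0.5, b = 0.5,
                          orientation = 0, kind = "filamentary")
  h <- 0.05
  cs <- rasterize_cross_section(pop, h, n_background = 1.33 + 0i)
  n_void <- sum(cs$index_map == cs$n_void)
  expect_lt(abs(n_void - pi * (0.5 / h)^2) / (pi * (0.5 / h)^2), 0.05)
})

test_that("a sericin band is rasterized void-free", {
  pop <- sample_void_population(0, fiber_radius = 5, seed = 1)
  pop$voids <- data.frame(x = 0, y = 0, a = 0.5, b = 0.5,
                          orientation = 0, kind = "filamentary")
  cs <- rasterize_cross_section(pop, 0.05, n_background = 1.33 + 0i,
                                sericin_band = c(-1, 1, -1, 1))
  expect_false(any(cs$index_map == cs$n_void))
  # same void without the band does rasterize
  cs2 <- rasterize_cross_section(pop, 0.05, n_background = 1.33 + 0i)
  expect_gt(sum(cs2$index_map == cs2$n_void), 0)
})

test_that("too-coarse grids are refused with the required spacing", {
  pop <- sample_void_population(2.2, fiber_radius = 5, seed = 2)
  expect_error(rasterize_cross_section(pop, 0.2),
               class = "silkphotonics_grid_error")
})

test_that("invariant mode returns identical maps at all z", {
  cs <- tiny_cross_section(seed = 9)
  med <- longitudinal_index_sequence(cs, "invariant",
                                     z_positions = c(0, 10, 20))
  expect_identical(med$planes[[1]]$index_map, med$planes[[3]]$index_map)
})

test_that("morphing void centers follow a sqrt(dz) random walk", {
  cs <- tiny_cross_section(density = 1.0, fiber_radius = 10, seed = 4,
                           grid_spacing = 0.08, margin = 2)
  corr_len <- 50
  z <- seq(0, 40, by = 5)
  med <- longitudinal_index_sequence(cs, "morphing",
                                     correlation_length = corr_len,
                                     z_positions = z, seed = 6)
  v0 <- cs$population$voids
  scale <- mean((v0$a + v0$b) / 2)
  disp <- vapply(seq_along(z), function(i) {
    vi <- med$planes[[i]]$population$voids
    sqrt(mean((vi$x - v0$x)^2 + (vi$y - v0$y)^2))
  }, 0)
  # rms displacement at z should be ~ scale * sqrt(2 * z / corr) (2D walk)
  expected <- scale * sqrt(2 * z / corr_len)
  expect_lt(max(abs(disp[-1] - expected[-1])), 3 * max(expected))
  # monotone growth of rms displacement
  expect_gt(stats::cor(z, disp, method = "spearman"), 0.9)
  # sizes stay fixed
  expect_equal(med$planes[[length(z)]]$population$voids$a, v0$a)
})

test_that("particulate planes are statistically independent", {
  cs <- tiny_cross_section(density = 2.2, fiber_radius = 8, seed = 4,
                           grid_spacing = 0.08, margin = 2)
  med <- longitudinal_index_sequence(cs, "particulate",
                                     z_positions = c(0, 10), seed = 12)
  a <- med$planes[[1]]$population$voids
  b <- med$planes[[2]]$population$voids
  # nearest-neighbor distances between the two sets should look Poisson:
  # mean NN distance for intensity rho is 1/(2 sqrt(rho))
  nn <- vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2))
  }, 0)
  rho <- nrow(b) / (pi * 8^2)
  expect_gt(mean(nn), 0.5 / (2 * sqrt(rho)))
  expect_lt(mean(nn), 2.0 / (2 * sqrt(rho)))
})

test_that("populations round-trip through JSON", {
  pop <- sample_void_population(2.2, fiber_radius = 6, seed = 8)
  path <- tempfile(fileext = ".json")
  write_population_json(pop, path)
  back <- read_population_json(path)
  expect_equal(back$voids$x, pop$voids$x, tolerance = 1e-12)
  expect_equal(back$fiber_radius, pop$fiber_radius)
  expect_equal(back$seed, pop$seed)
})
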