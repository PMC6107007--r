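# Shared helpers: small deterministic fixtures built in code.

# A modest disordered cross-section for propagation tests.
tiny_cross_section <- function(density = 2.2, fiber_radius = 5, seed = 42,
                               grid_spacing = 0.078, margin = 3.2, ...) {
  pop <- sample_void_population(density, fiber_radius = fiber_radius,
                                seed = seed, ...)
  rasterize_cross_section(pop, grid_spacing, margin = margin)
}

# Uniform (void-free, index-matched) medium: pure free space on the grid.
free_space_section <- function(fiber_radius = 5, grid_spacing = 0.078,
                               margin = 3.2) {
  pop <- sample_void_population(0, fiber_radius = fiber_radius, seed = 1)
  rasterize_cross_section(pop, grid_spacing, n_matrix = 1 + 0i,
                          n_void = 1 + 0i, n_background = 1 + 0i,
                          margin = margin)
}

# Radially symmetric exponential intensity image I(r) = exp(-2 r / xi).
exponential_image <- function(xi, n = 201, h = 0.1) {
  coord <- (seq_len(n) - (n + 1) / 2) * h
  img <- exp(-2 * sqrt(outer(coord^2, coord^2, "+")) / xi)
  attr(img, "grid_spacing") <- h
  attr(img, "x") <- coord
  attr(img, "y") <- coord
  img
}

# Gaussian intensity image with standard deviation sigma.
gaussian_image <- function(sigma, n = 201, h = 0.1, center = c(0, 0),
                           height = 1) {
  coord <- (seq_len(n) - (n + 1) / 2) * h
  r2 <- outer((coord - center[1])^2, (coord - center[2])^2, "+")
  img <- height * exp(-r2 / (2 * sigma^2))
  attr(img, "grid_spacing") <- h
  attr(img, "x") <- coord
  attr(img, "y") <- coord
  img
}
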