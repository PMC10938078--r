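# Shared fixtures: reference Clebsch-Gordan values (frozen from an exact
# symbolic computation), random-solution builders, and quadrature helpers.

# columns: l1 m1 l2 m2 L M value  (exact values: sqrt(3)/3, sqrt(6)/3, ...)
cg_reference <- rbind(
  c(0, 0, 0, 0, 0, 0, 1),
  c(1, 1, 1, -1, 0, 0, 0.5773502691896257),
  c(1, 0, 1, 0, 2, 0, 0.8164965809277260),
  c(2, 1, 1, -1, 1, 0, 0.5477225575051661),
  c(2, 1, 1, -1, 2, 0, 0.7071067811865476),
  c(2, 1, 1, -1, 3, 0, 0.4472135954999579),
  c(3, 2, 2, -1, 1, 1, -0.5345224838248488),
  c(3, 2, 2, -1, 5, 1, 0.3380617018914066),
  c(2, 0, 1, 0, 1, 0, -0.6324555320336759),
  c(2, 0, 1, 0, 3, 0, 0.7745966692414834),
  c(4, 3, 1, 1, 5, 4, 0.8944271909999159),
  c(4, 3, 1, -1, 3, 2, 0.7637626158259734),
  c(3, -2, 3, 1, 4, -1, 0.4558423058385518),
  c(2, 2, 2, -2, 0, 0, 0.4472135954999579),
  c(6, 1, 1, 0, 5, 1, -0.6698641270570836),
  c(6, 1, 1, 0, 7, 1, 0.7262730392025629)
)

# random elastic solution with boundary degree N (conjugate-symmetric
# displacement, nonzero monopole via an r0 offset)
random_solution <- function(N, seed, r0 = 1, nu = 0.33, G = 1,
                            amplitude = 0.12, include_degree1 = FALSE) {
  shape <- make_random_shape(r0 * 0.98, N, amplitude = amplitude, seed = seed,
                             include_degree1 = include_degree1)
  geom <- displacement_coeffs(shape, r0)
  solve_elastic(geom, material(G, nu))
}

# points uniform in a radial shell [rmin, rmax] * r0
random_shell_points <- function(k, r0, rmin, rmax, seed) {
  set.seed(seed)
  dir <- matrix(stats::rnorm(3 * k), k, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * (r0 * stats::runif(k, rmin, rmax))
}

# dense quadrature of (1/3) * integral of s^3 over the sphere (volume oracle)
volume_oracle <- function(shape, ntheta = 200, nphi = 256) {
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  grid <- expand.grid(x = gl$x, phi = phi)
  w <- rep(gl$w, nphi) * (2 * pi / nphi)
  s <- radius_function(shape, acos(grid$x), grid$phi)
  sum(w * s^3) / 3
}

# quadrature of f(theta, phi) over the sphere (triple-product oracle etc.)
sphere_integral <- function(f, ntheta = 60, nphi = 96) {
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  grid <- expand.grid(x = gl$x, phi = phi)
  w <- rep(gl$w, nphi) * (2 * pi / nphi)
  sum(w * f(acos(grid$x), grid$phi))
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(expected), 1e-300)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
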