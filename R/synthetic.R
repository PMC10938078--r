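# Synthetic-data module: shape generators and surface-point sampling emulating
# microscopy-derived bead surfaces, so every pipeline stage is testable without
# experimental data.

#' Spherical shape expansion
#'
#' @param r1 Sphere radius.
#' @return An [sh_expansion()] with \eqn{s_{00} = \sqrt{4\pi}\, r_1} and all
#'   other coefficients zero.
#' @export
make_sphere_shape <- function(r1) {
  stopifnot(r1 > 0)
  coef <- rep(0 + 0i, 1)
  coef[sh_index(0, 0)] <- sqrt(4 * pi) * r1
  sh_expansion(0L, coef)
}

#' Uniaxially deformed shape
#'
#' \eqn{s(\theta,\phi) = \sqrt{4\pi}\, r_0 Y_{00} + d_{20} Y_{20}}: a sphere
#' with a single zonal quadrupole mode, the standard test case for deformation
#' along one axis.
#'
#' @param r0 Base radius.
#' @param d20 Real coefficient of \eqn{Y_{20}} (length units); `|d20| < r0`.
#' @return An [sh_expansion()] of degree 2.
#' @export
make_uniaxial_shape <- function(r0, d20) {
  stopifnot(r0 > 0, abs(d20) < r0)
  coef <- rep(0 + 0i, sh_size(2L))
  coef[sh_index(0, 0)] <- sqrt(4 * pi) * r0
  coef[sh_index(2, 0)] <- d20
  sh_expansion(2L, coef)
}

#' Random smooth star-shaped surface
#'
#' Draws a conjugate-symmetric expansion around radius `r0` with coefficient
#' scale decaying as \eqn{n^{-2}} (emulating the smooth bead surfaces seen in
#' tissue): for \eqn{2 \le n \le N} each independent coefficient has standard
#' deviation `amplitude * r0 / n^2`.  Degree-1 modes are zero by default (no
#' spurious rigid translation).
#'
#' @param r0 Base radius.
#' @param N Maximum degree (`N >= 2`).
#' @param amplitude Relative deformation scale; values up to 0.3 stay in the
#'   linear-elastic regime.
#' @param seed Integer seed for reproducibility.
#' @param include_degree1 If `TRUE`, degree-1 modes are drawn too (useful for
#'   testing recentering).
#' @return An [sh_expansion()].
#' @export
make_random_shape <- function(r0, N, amplitude = 0.1, seed = 1,
                              include_degree1 = FALSE) {
  stopifnot(r0 > 0, N >= 2)
  if (amplitude > 0.3) {
    warning("amplitude > 0.3 leaves the linear-elastic regime")
  }
  set.seed(as.integer(seed))
  coef <- rep(0 + 0i, sh_size(N))
  coef[sh_index(0, 0)] <- sqrt(4 * pi) * r0
  n_from <- if (include_degree1) 1L else 2L
  for (n in n_from:N) {
    sd_n <- amplitude * r0 / n^2
    coef[sh_index(n, 0)] <- stats::rnorm(1, sd = sd_n)
    for (m in 1:n) {
      v <- complex(real = stats::rnorm(1, sd = sd_n / sqrt(2)),
                   imaginary = stats::rnorm(1, sd = sd_n / sqrt(2)))
      coef[sh_index(n, m)] <- v
      coef[sh_index(n, -m)] <- (-1)^m * Conj(v)
    }
  }
  sh_expansion(N, coef)
}

#' Sample surface points from a shape expansion
#'
#' Draws directions uniformly on the sphere (area-uniform: \eqn{\cos\theta}
#' uniform, \eqn{\phi} uniform — matching scattered microscopy points rather
#' than a grid), places points at radius \eqn{s(\theta,\phi)}, and adds
#' isotropic 3D Gaussian noise of scale `noise_sd`.
#'
#' @param shape An [sh_expansion()] of the radius function.
#' @param npoints Number of points.
#' @param noise_sd Noise standard deviation per Cartesian coordinate (length
#'   units; 0 for noiseless).
#' @param seed Integer seed.
#' @return A [point_cloud()] centered at the origin.
#' @export
sample_surface_points <- function(shape, npoints, noise_sd = 0, seed = 1) {
  stopifnot(npoints >= 4, noise_sd >= 0)
  set.seed(as.integer(seed))
  ct <- stats::runif(npoints, -1, 1)
  theta <- acos(ct)
  phi <- stats::runif(npoints, 0, 2 * pi)
  s <- radius_function(shape, theta, phi)
  if (any(s <= 0)) stop("shape radius non-positive at sampled angles")
  pts <- cbind(s * sin(theta) * cos(phi), s * sin(theta) * sin(phi), s * ct)
  if (noise_sd > 0) {
    pts <- pts + matrix(stats::rnorm(3 * npoints, sd = noise_sd), npoints, 3)
  }
  point_cloud(pts, center = c(0, 0, 0))
}
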