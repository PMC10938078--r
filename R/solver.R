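# Solver module: converts the radial boundary condition into the Love/Trefftz
# potentials (harmonic vector field U via K_nm, harmonic scalar psi via a_nm)
# and evaluates the displacement field u = U + (r^2 - r0^2) grad(psi).
#
# Storage conventions.  Public coefficients follow the continuous two-branch
# normalization: interior U = sum (r/r0)^n K_nm Y_nm, exterior
# U = sum (r0/r)^{n+1} K_nm Y_nm (same for psi with a_nm), so one coefficient
# table describes both branches.  Internally, "plain" coefficients (of r^n Y_nm
# or Y_nm/r^{n+1}) are used for gradient algebra.

#' Linear-elastic material parameters
#'
#' @param G Shear modulus, Pa (`G > 0`).
#' @param nu Poisson's ratio, strictly below 0.5 (the ansatz couplings contain
#'   `1/(1-2*nu)`); `-1 < nu < 0.5`.
#' @return Object of class `material`.
#' @export
material <- function(G, nu) {
  if (!(G > 0)) stop("shear modulus G must be positive")
  if (!(nu > -1 && nu < 0.5)) {
    stop("Poisson's ratio must satisfy -1 < nu < 0.5 (nu = 0.5 is singular ",
         "in the compressible formulation)")
  }
  structure(list(G = G, nu = nu), class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material> G =", x$G, "Pa, nu =", x$nu, "\n")
  invisible(x)
}

# Cartesian components of the radial unit vector in degree-1 harmonics:
# e_r = sqrt(2*pi/3) * ( Y_{1,-1} - Y_{1,1},  i (Y_{1,-1} + Y_{1,1}),  sqrt(2) Y_{1,0} )
er_beta <- function(mu) {
  switch(as.character(mu),
         "-1" = c(sqrt(2 * pi / 3), 1i * sqrt(2 * pi / 3), 0),
         "0"  = c(0, 0, sqrt(4 * pi / 3)),
         "1"  = c(-sqrt(2 * pi / 3), 1i * sqrt(2 * pi / 3), 0))
}

#' Cartesian harmonic expansion of the radial boundary displacement
#'
#' Expresses \eqn{u|_{r_0} = \sum d_{nm} Y_{nm} \hat e_r} in Cartesian
#' components: each component is a sum of products \eqn{Y_{nm} Y_{1\mu}} that is
#' linearized into single harmonics with Clebsch-Gordan coefficients, and the
#' degree-L content of each component is collected into the vector coefficient
#' \eqn{K_{LM}}.  The result extends one degree beyond the boundary expansion
#' (`N + 1`, the product with the degree-1 radial unit vector).
#'
#' @param geom A [displacement_coeffs()] result (`bead_geometry`).
#' @return Object of class `vector_boundary_expansion`: list with `N` and `K`,
#'   a `(N+1)^2 x 3` complex matrix of Cartesian components.
#' @export
boundary_to_cartesian <- function(geom) {
  stopifnot(inherits(geom, "bead_geometry"))
  N <- geom$dnm$N
  NK <- N + 1L
  K <- matrix(0 + 0i, sh_size(NK), 3)
  d <- geom$dnm$coef
  for (n in 0:N) {
    for (m in -n:n) {
      dd <- d[sh_index(n, m)]
      if (dd == 0) next
      for (mu in -1:1) {
        lin <- linearize_sh_product(n, m, 1, mu)
        if (nrow(lin) == 0) next
        beta <- er_beta(mu)
        for (k in seq_len(nrow(lin))) {
          idx <- sh_index(lin$L[k], lin$M[k])
          K[idx, ] <- K[idx, ] + dd * lin$coef[k] * beta
        }
      }
    }
  }
  structure(list(N = NK, K = K, r0 = geom$r0), class = "vector_boundary_expansion")
}

#' @export
print.vector_boundary_expansion <- function(x, ...) {
  cat("<vector_boundary_expansion> degree N =", x$N, "\n")
  invisible(x)
}

# plain (r^n Y_nm) Cartesian coefficients of the interior branch of U
k_plain <- function(K, N, r0) {
  scl <- r0^(-sh_degree_of_slot(N))
  K * scl
}

#' Divergence of the harmonic vector field U
#'
#' Applies the solid-harmonic gradient ladder to each Cartesian component of
#' the interior branch of U (the `(r/r0)^n` scaling folded in) and collects
#' \eqn{\nabla \cdot U} as an expansion in plain solid harmonics: the entry
#' indexed `(n, m)` holds the coefficient of \eqn{r^{n-1} Y_{n-1,m}}
#' originating from the degree-`n` part of U.
#'
#' @param K A [boundary_to_cartesian()] result.
#' @param r0 Initial sphere radius.
#' @return Object of class `divergence_expansion` with fields `N` (= degree of
#'   K) and `c` (complex vector indexed like a degree-`N` expansion; slots with
#'   `n = 0` are unused).
#' @export
divergence_coeffs <- function(K, r0 = K$r0) {
  stopifnot(inherits(K, "vector_boundary_expansion"), r0 > 0)
  NK <- K$N
  Ks <- k_plain(K$K, NK, r0)
  gx <- grad_regular_expansion(Ks[, 1], NK)
  gy <- grad_regular_expansion(Ks[, 2], NK)
  gz <- grad_regular_expansion(Ks[, 3], NK)
  b <- if (gx$zero) complex(1) else gx$x + gy$y + gz$z   # degree NK-1 plain coeffs
  cvec <- rep(0 + 0i, sh_size(NK))
  if (NK >= 1) {
    for (n in 1:NK) for (m in -(n - 1):(n - 1)) {
      cvec[sh_index(n, m)] <- b[sh_index(n - 1L, m)]
    }
  }
  structure(list(N = NK, c = cvec, r0 = r0), class = "divergence_expansion")
}

# Love/Trefftz coupling denominator: psi_{n-1} = (div U)_n / psi_denominator(n).
# Derived by substituting u = U + (r^2 - r0^2) grad(psi) into the Navier-Lame
# equation and matching homogeneous degrees (Euler's theorem); validated by the
# finite-difference Navier oracle in the test suite.
psi_denominator <- function(n, nu) 2 * (2 * nu * (2 * n - 1) - 3 * n + 2)

#' Scalar-potential coefficients from the divergence of U
#'
#' The ansatz couples the degree-`(n-1)` part of \eqn{\psi} to the degree-`n`
#' part of \eqn{\nabla\cdot U}:
#' \eqn{a_{n-1,m} \propto c_{nm} / (2(2\nu(2n-1) - 3n + 2))}.
#' Degree-0 coefficients of \eqn{\psi} are retained: they are gauge for the
#' displacement (constants vanish under the gradient) but enter the expanded
#' stress-series bookkeeping.
#'
#' @param cdiv A [divergence_coeffs()] result.
#' @param nu Poisson's ratio (`nu < 0.5`).
#' @param r0 Initial sphere radius.
#' @return Object of class `scalar_potential_expansion` with fields `N`
#'   (= degree of K minus 1) and `a`, coefficients in the two-branch
#'   normalization of the potential (interior \eqn{(r/r_0)^n a_{nm} Y_{nm}}).
#' @export
psi_coeffs <- function(cdiv, nu, r0 = cdiv$r0) {
  stopifnot(inherits(cdiv, "divergence_expansion"))
  if (!(nu < 0.5)) stop("nu must be below 0.5")
  NK <- cdiv$N
  Na <- NK - 1L
  a <- rep(0 + 0i, sh_size(max(Na, 0L)))
  if (NK >= 1) {
    for (n in 1:NK) {
      D <- psi_denominator(n, nu)
      if (abs(D) < 1e-14) {
        stop("singular ansatz coupling at degree n = ", n, ", nu = ", nu)
      }
      for (m in -(n - 1):(n - 1)) {
        a[sh_index(n - 1L, m)] <- cdiv$c[sh_index(n, m)] * r0^(n - 1) / D
      }
    }
  }
  structure(list(N = max(Na, 0L), a = a, r0 = r0),
            class = "scalar_potential_expansion")
}

#' Solve the elastic boundary-value problem for a radially displaced sphere
#'
#' Composes [boundary_to_cartesian()], [divergence_coeffs()] and [psi_coeffs()]
#' into a complete solution of the Navier-Lame equation with the given radial
#' boundary displacement: `u = U + (r^2 - r0^2) grad(psi)` with harmonic `U`
#' (coefficients `K`) and harmonic `psi` (coefficients `a`).
#'
#' @param geom A `bead_geometry` from [displacement_coeffs()].
#' @param mat A [material()].
#' @return Object of class `elastic_solution` bundling `r0`, `material`, `K`
#'   (vector boundary expansion) and `a` (scalar potential expansion).
#' @export
solve_elastic <- function(geom, mat) {
  stopifnot(inherits(geom, "bead_geometry"), inherits(mat, "material"))
  K <- boundary_to_cartesian(geom)
  cdiv <- divergence_coeffs(K, geom$r0)
  a <- psi_coeffs(cdiv, mat$nu, geom$r0)
  structure(list(r0 = geom$r0, material = mat, K = K, a = a,
                 boundary_degree = geom$dnm$N,
                 displacement_sign = geom$displacement_sign),
            class = "elastic_solution")
}

#' @export
print.elastic_solution <- function(x, ...) {
  cat("<elastic_solution> r0 =", signif(x$r0, 6),
      ", boundary degree", x$boundary_degree,
      ", G =", x$material$G, "Pa, nu =", x$material$nu, "\n")
  invisible(x)
}

# plain interior coefficients of psi (of r^n Y_nm)
a_plain <- function(sol) {
  sol$a$a * sol$r0^(-sh_degree_of_slot(sol$a$N))
}

#' Evaluate the harmonic potentials of a solution
#'
#' Evaluates the scalar potential \eqn{\psi} and the Cartesian components of
#' the vector potential \eqn{U}, using the regular-harmonic branch for
#' `r <= r0` and the irregular branch (decaying at infinity) for `r > r0`; the
#' two branches match continuously at `r0`, except that the degree-0 term of
#' \eqn{\psi} — a constant inside the bead, hence pure gauge for the
#' displacement — is continued by zero outside so that the displacement field
#' decays at infinity.
#'
#' @param sol An [solve_elastic()] result.
#' @param points k x 3 Cartesian positions.
#' @return List with `psi` (numeric k-vector) and `U` (k x 3 matrix).
#' @export
potential_fields <- function(sol, points) {
  points <- as_points(points)
  r <- sqrt(rowSums(points^2))
  interior <- r <= sol$r0
  NK <- sol$K$N
  Na <- sol$a$N
  psi <- rep(NA_complex_, nrow(points))
  U <- matrix(NA_complex_, nrow(points), 3)
  if (any(interior)) {
    P <- points[interior, , drop = FALSE]
    aP <- a_plain(sol)
    psi[interior] <- eval_regular_expansion(aP, Na, P)
    Ks <- k_plain(sol$K$K, NK, sol$r0)
    for (j in 1:3) U[interior, j] <- eval_regular_expansion(Ks[, j], NK, P)
  }
  if (any(!interior)) {
    P <- points[!interior, , drop = FALSE]
    degK <- sh_degree_of_slot(NK)
    dega <- sh_degree_of_slot(Na)
    ae <- sol$a$a * sol$r0^(dega + 1)     # plain irregular coeffs (of Y/r^{n+1})
    ae[sh_index(0, 0)] <- 0               # degree-0 gauge continued by zero
    Ke <- sol$K$K * sol$r0^(degK + 1)
    psi[!interior] <- eval_irregular_expansion(ae, Na, P)
    for (j in 1:3) U[!interior, j] <- eval_irregular_expansion(Ke[, j], NK, P)
  }
  list(psi = finite_real(psi, "psi"), U = finite_real(U, "U"))
}

finite_real <- function(z, what) {
  scale <- max(abs(z), 1e-300)
  if (max(abs(Im(z))) > 1e-8 * scale) {
    warning(what, " has non-negligible imaginary residual ",
            format(max(abs(Im(z)))))
  }
  if (is.null(dim(z))) Re(z) else array(Re(z), dim = dim(z))
}

#' Displacement field of an elastic solution
#'
#' \eqn{u = U + (r^2 - r_0^2)\nabla\psi}, interior branch for `r <= r0`,
#' exterior (decaying) branch for `r > r0`; the field is continuous at `r0`,
#' where it equals the boundary displacement.
#'
#' @param sol An `elastic_solution`.
#' @param points k x 3 Cartesian positions (or a length-3 vector).
#' @return Real k x 3 matrix of Cartesian displacement components.
#' @export
displacement_field <- function(sol, points) {
  points <- as_points(points)
  r2 <- rowSums(points^2)
  r <- sqrt(r2)
  interior <- r <= sol$r0
  out <- matrix(NA_complex_, nrow(points), 3)
  NK <- sol$K$N
  Na <- sol$a$N
  if (any(interior)) {
    P <- points[interior, , drop = FALSE]
    Ks <- k_plain(sol$K$K, NK, sol$r0)
    U <- sapply(1:3, function(j) eval_regular_expansion(Ks[, j], NK, P))
    U <- matrix(U, ncol = 3)
    g <- grad_regular_expansion(a_plain(sol), Na)
    gp <- if (g$zero) matrix(0 + 0i, nrow(P), 3) else {
      matrix(sapply(list(g$x, g$y, g$z),
                    function(cc) eval_regular_expansion(cc, g$N, P)), ncol = 3)
    }
    out[interior, ] <- U + (r2[interior] - sol$r0^2) * gp
  }
  if (any(!interior)) {
    P <- points[!interior, , drop = FALSE]
    degK <- sh_degree_of_slot(NK)
    dega <- sh_degree_of_slot(Na)
    Ke <- sol$K$K * sol$r0^(degK + 1)
    ae <- sol$a$a * sol$r0^(dega + 1)
    # the degree-0 scalar-potential term is gauge inside the bead (a constant)
    # but its irregular continuation Y00/r is not; continuing it by zero keeps
    # (r^2 - r0^2) grad(psi), hence u, decaying at infinity
    ae[sh_index(0, 0)] <- 0
    U <- matrix(sapply(1:3, function(j) eval_irregular_expansion(Ke[, j], NK, P)),
                ncol = 3)
    g <- grad_irregular_expansion(ae, Na)
    gp <- matrix(sapply(list(g$x, g$y, g$z),
                        function(cc) eval_irregular_expansion(cc, g$N, P)),
                 ncol = 3)
    out[!interior, ] <- U + (r2[!interior] - sol$r0^2) * gp
  }
  finite_real(out, "displacement field")
}

#' Finite-difference residual of the Navier-Lame equation
#'
#' Evaluates \eqn{\frac{1}{1-2\nu}\nabla(\nabla\cdot u) + \nabla^2 u} by
#' central differences at an interior point.  The relative residual compares
#' the (vector) residual magnitude against the larger of the two constituent
#' terms and the curvature scale \eqn{|u|/r_0^2}, so a correct solution scores
#' near the FD truncation floor while any miscoupled coefficient registers as
#' an O(1) violation.
#'
#' @param sol An `elastic_solution`.
#' @param point Length-3 Cartesian position, interior, at least `2h` away from
#'   both the origin region and the `r0` interface (the two-branch field is
#'   only C0-matched there).
#' @param h FD step (default `1e-4 * r0`).
#' @return List with `residual` (3-vector) and `rel` (scalar relative residual).
#' @export
navier_residual <- function(sol, point, h = 1e-4 * sol$r0) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3)
  r <- sqrt(sum(point^2))
  if (r >= sol$r0 - 2 * h) {
    stop("stencil placement: point must be interior, > 2h below r0")
  }
  nu <- sol$material$nu
  E <- diag(3)
  u0 <- displacement_field(sol, matrix(point, 1))
  divu <- function(p) {
    s <- 0
    for (i in 1:3) {
      s <- s + (displacement_field(sol, matrix(p + h * E[i, ], 1))[i] -
                  displacement_field(sol, matrix(p - h * E[i, ], 1))[i]) / (2 * h)
    }
    s
  }
  graddiv <- vapply(1:3, function(i) {
    (divu(point + h * E[i, ]) - divu(point - h * E[i, ])) / (2 * h)
  }, numeric(1))
  lap <- vapply(1:3, function(j) {
    s <- -6 * u0[j]
    for (i in 1:3) {
      s <- s + displacement_field(sol, matrix(point + h * E[i, ], 1))[j] +
        displacement_field(sol, matrix(point - h * E[i, ], 1))[j]
    }
    s / h^2
  }, numeric(1))
  res <- graddiv / (1 - 2 * nu) + lap
  den <- max(sqrt(sum((graddiv / (1 - 2 * nu))^2)), sqrt(sum(lap^2)),
             sqrt(sum(u0^2)) / sol$r0^2)
  list(residual = res, rel = sqrt(sum(res^2)) / den)
}

#' Finite-difference Laplacian of a scalar field
#'
#' Validation utility: seven-point central-difference Laplacian with the
#' relative residual normalized by `max |f| / h^2` over the stencil, the
#' natural scale against which the cancellation of a harmonic function is
#' measured.
#'
#' @param f Function mapping a k x 3 matrix to a numeric k-vector.
#' @param point Length-3 position.
#' @param h Step size.
#' @return List with `laplacian` and `rel`.
#' @export
fd_laplacian <- function(f, point, h) {
  E <- diag(3)
  pts <- rbind(matrix(point, 1),
               do.call(rbind, lapply(1:3, function(i) {
                 rbind(point + h * E[i, ], point - h * E[i, ])
               })))
  v <- f(pts)
  lap <- (sum(v[-1]) - 6 * v[1]) / h^2
  list(laplacian = lap, rel = abs(lap) * h^2 / max(abs(v)))
}
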