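# Stress module: assembles the stress (and strain) tensor fields of an elastic
# solution inside the bead, provides the closed-form isotropic special case,
# the expanded per-harmonic series route, and finite-difference oracles.

#' Stress tensor container
#'
#' @param components Real symmetric 3x3 matrix, Pa.
#' @param basis `"cartesian"` or `"spherical"` (\eqn{e_r, e_\theta, e_\phi}).
#' @param location Spherical coordinates `c(r, theta, phi)` of the evaluation
#'   point (may be `NULL` for location-free tensors).
#' @return Object of class `stress_tensor`.
#' @export
stress_tensor_obj <- function(components, basis = c("cartesian", "spherical"),
                              location = NULL) {
  basis <- match.arg(basis)
  components <- as.matrix(components)
  stopifnot(all(dim(components) == c(3, 3)))
  asym <- max(abs(components - t(components)))
  if (asym > 1e-8 * max(abs(components), 1e-300)) {
    warning("stress tensor deviates from symmetry by ", format(asym))
  }
  components <- (components + t(components)) / 2
  structure(list(components = components, basis = basis, location = location),
            class = "stress_tensor")
}

#' @export
print.stress_tensor <- function(x, ...) {
  cat("<stress_tensor> basis:", x$basis, "\n")
  print(signif(x$components, 6))
  invisible(x)
}

# interior-point guard shared by the stress evaluators
check_interior <- function(r, r0) {
  if (r > r0 * (1 + 1e-9)) {
    stop("stress evaluation requested at r = ", format(r),
         " outside the bead (r0 = ", format(r0), "); exterior stress is not ",
         "defined by the bead's moduli")
  }
}

sph_to_cart_point <- function(r, theta, phi) {
  c(r * sin(theta) * cos(phi), r * sin(theta) * sin(phi), r * cos(theta))
}

# evaluate gradient-expansion list at a single point (returns complex 3-vector)
eval_grad_at <- function(g, point) {
  if (isTRUE(g$zero)) return(rep(0 + 0i, 3))
  vapply(list(g$x, g$y, g$z),
         function(cc) eval_regular_expansion(cc, g$N, matrix(point, 1)),
         complex(1))
}

#' Stress tensor of an elastic solution (direct route)
#'
#' Evaluates, analytically from the solid-harmonic expansions,
#' \deqn{\hat T = 2G\Big(\frac{\nu}{1-2\nu}(\nabla\cdot U + 2 r\cdot\nabla\psi)\hat E
#'   + \mathrm{Def}(U) + r\otimes\nabla\psi + (r\otimes\nabla\psi)^T
#'   + (r^2 - r_0^2)\nabla\otimes\nabla\psi\Big)}
#' at an interior point (the origin is allowed).  This is the reference
#' implementation; [stress_tensor_expanded()] is the per-harmonic series form
#' checked against it.
#'
#' @param sol An [solve_elastic()] result.
#' @param r,theta,phi Spherical coordinates of the evaluation point,
#'   `r <= r0`.
#' @return A [stress_tensor_obj()] in the Cartesian basis.
#' @export
stress_tensor <- function(sol, r, theta, phi) {
  check_interior(r, sol$r0)
  p <- sph_to_cart_point(r, theta, phi)
  G <- sol$material$G
  nu <- sol$material$nu
  NK <- sol$K$N
  Na <- sol$a$N
  Ks <- k_plain(sol$K$K, NK, sol$r0)
  aP <- a_plain(sol)
  gU <- lapply(1:3, function(j) grad_regular_expansion(Ks[, j], NK))
  gradU <- matrix(0 + 0i, 3, 3)     # gradU[i, j] = d_i U_j
  for (j in 1:3) gradU[, j] <- eval_grad_at(gU[[j]], p)
  divU <- sum(diag(gradU))
  gpsi_exp <- grad_regular_expansion(aP, Na)
  gpsi <- eval_grad_at(gpsi_exp, p)
  hess <- matrix(0 + 0i, 3, 3)      # hess[i, j] = d_i d_j psi
  if (!gpsi_exp$zero) {
    for (j in c("x", "y", "z")) {
      gg <- grad_regular_expansion(gpsi_exp[[j]], gpsi_exp$N)
      hess[, match(j, c("x", "y", "z"))] <- eval_grad_at(gg, p)
    }
  }
  DefU <- (gradU + t(gradU)) / 2
  rgp <- outer(p, gpsi)             # r (x) grad psi
  Tm <- 2 * G * (nu / (1 - 2 * nu) * (divU + 2 * sum(p * gpsi)) * diag(3) +
                   DefU + rgp + t(rgp) + (r^2 - sol$r0^2) * hess)
  Tm <- as_real_tensor(Tm)
  stress_tensor_obj(Tm, basis = "cartesian", location = c(r, theta, phi))
}

as_real_tensor <- function(Tm) {
  scale <- max(abs(Tm), 1e-300)
  if (max(abs(Im(Tm))) > 1e-8 * scale) {
    warning("stress tensor has non-negligible imaginary residual ",
            format(max(abs(Im(Tm)))))
  }
  matrix(Re(Tm), 3, 3)
}

#' Stress tensor via the expanded per-harmonic series
#'
#' Assembles the same tensor as [stress_tensor()] as an explicit sum over the
#' coefficients \eqn{a_{nm}} and \eqn{K_{nm}}.  Two exact simplifications
#' distinguish this route from the direct one: Euler's theorem turns
#' \eqn{r\cdot\nabla} into multiplication by the degree, and the ansatz
#' coupling collapses the isotropic term to
#' \eqn{-2\nu \sum_{nm} (2n+1)\, a_{nm}\, (r/r_0)^n Y_{nm}\, \hat E}
#' (the \eqn{1/(1-2\nu)} fraction cancels against the coupling denominator).
#' Agreement with the direct route therefore certifies the series
#' transcription.
#'
#' @inheritParams stress_tensor
#' @return A [stress_tensor_obj()] in the Cartesian basis.
#' @export
stress_tensor_expanded <- function(sol, r, theta, phi) {
  check_interior(r, sol$r0)
  p <- sph_to_cart_point(r, theta, phi)
  P1 <- matrix(p, 1)
  G <- sol$material$G
  nu <- sol$material$nu
  NK <- sol$K$N
  Na <- sol$a$N
  Ks <- k_plain(sol$K$K, NK, sol$r0)
  aP <- a_plain(sol)
  Tm <- matrix(0 + 0i, 3, 3)
  # psi terms, per (n, m): isotropic part, r (x) grad, and Hessian
  for (n in 0:Na) {
    for (m in -n:n) {
      anm <- aP[sh_index(n, m)]
      if (anm == 0) next
      Rnm <- eval_regular_expansion(unit_coef(n, m), n, P1)
      Tm <- Tm - 2 * nu * (2 * n + 1) * anm * Rnm * diag(3)
      if (n >= 1) {
        gR <- grad_single(n, m)
        gval <- eval_grad_at(gR, p)
        rg <- outer(p, gval)
        Tm <- Tm + anm * (rg + t(rg))
        if (n >= 2) {
          H <- matrix(0 + 0i, 3, 3)
          for (j in 1:3) {
            gg <- grad_regular_expansion(list(gR$x, gR$y, gR$z)[[j]], gR$N)
            H[, j] <- eval_grad_at(gg, p)
          }
          Tm <- Tm + (r^2 - sol$r0^2) * anm * H
        }
      }
    }
  }
  # Def(U) terms, per (n, m): (K (x) grad R + grad R (x) K) / 2
  for (n in 1:NK) {
    for (m in -n:n) {
      Kv <- Ks[sh_index(n, m), ]
      if (all(Kv == 0)) next
      gR <- grad_single(n, m)
      gval <- eval_grad_at(gR, p)
      KG <- outer(Kv, gval)
      Tm <- Tm + (KG + t(KG)) / 2
    }
  }
  Tm <- as_real_tensor(2 * G * Tm)
  stress_tensor_obj(Tm, basis = "cartesian", location = c(r, theta, phi))
}

unit_coef <- function(n, m) {
  v <- rep(0 + 0i, sh_size(n))
  v[sh_index(n, m)] <- 1
  v
}

grad_single <- function(n, m) grad_regular_expansion(unit_coef(n, m), n)

#' Spherical-basis components of a stress tensor
#'
#' Similarity transform of a Cartesian-basis tensor into the local orthonormal
#' frame \eqn{(e_r, e_\theta, e_\phi)} at the tensor's location:
#' \eqn{T_{rr} = e_r^T T e_r} etc.  At the poles the frame follows the
#' \eqn{\theta\to 0} limit convention \eqn{e_\theta \to (\cos\phi, \sin\phi, 0)},
#' \eqn{e_\phi \to (-\sin\phi, \cos\phi, 0)}.
#'
#' @param Tc A Cartesian-basis [stress_tensor_obj()] with known location.
#' @return A [stress_tensor_obj()] with `basis = "spherical"`; rows/columns
#'   ordered \eqn{(r, \theta, \phi)}.
#' @export
spherical_components <- function(Tc) {
  stopifnot(inherits(Tc, "stress_tensor"))
  if (Tc$basis == "spherical") return(Tc)
  if (is.null(Tc$location)) stop("location unknown; cannot build the local frame")
  th <- Tc$location[2]
  ph <- Tc$location[3]
  er <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  et <- c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
  ep <- c(-sin(ph), cos(ph), 0)
  Q <- unname(cbind(er, et, ep))
  stress_tensor_obj(t(Q) %*% Tc$components %*% Q, basis = "spherical",
                    location = Tc$location)
}

#' Closed-form stress of a uniformly deformed sphere
#'
#' A bead deformed from radius `r0` to radius `r1` while remaining spherical
#' carries an isotropic stress.  Direct evaluation of the uniform solution
#' through Hooke's law gives the scalar
#' \deqn{T = \frac{2G(1+\nu)}{1-2\nu}\,\frac{r_0 - r_1}{r_0}}
#' under the default boundary-displacement convention
#' \eqn{u|_{r_0} = (r_0 - s)\hat e_r} (negated for `"flipped"`).  The
#' prefactor is calibrated against the full pipeline on the uniform case; a
#' commonly quoted \eqn{8\pi G} variant presumes an unnormalized constant
#' harmonic and differs by a factor \eqn{4\pi}.
#'
#' @param mat A [material()].
#' @param r0 Initial radius. @param r1 Deformed radius.
#' @param displacement_sign Sign convention, as in [displacement_coeffs()].
#' @return A [stress_tensor_obj()] (Cartesian basis, location-free).
#' @export
isotropic_sphere_stress <- function(mat, r0, r1,
                                    displacement_sign = c("as-printed", "flipped")) {
  displacement_sign <- match.arg(displacement_sign)
  stopifnot(inherits(mat, "material"), r0 > 0)
  s <- 2 * mat$G * (1 + mat$nu) / (1 - 2 * mat$nu) * (r0 - r1) / r0
  if (displacement_sign == "flipped") s <- -s
  stress_tensor_obj(diag(s, 3), basis = "cartesian")
}

#' Strain tensor by finite differences of the displacement field
#'
#' \eqn{\hat\epsilon = \frac{1}{2}(\nabla u + (\nabla u)^T)} via central
#' differences.  Used as an independent validation path; pair with
#' [hooke_oracle_stress()].
#'
#' @inheritParams stress_tensor
#' @param h FD step (default `1e-5 * r0`); the point must be at least `2h`
#'   inside the `r0` interface.
#' @return Object of class `strain_tensor` (list with `components`, `basis`,
#'   `location`).
#' @export
strain_tensor <- function(sol, r, theta, phi, h = 1e-5 * sol$r0) {
  if (r >= sol$r0 - 2 * h) stop("stencil placement: need r < r0 - 2h")
  p <- sph_to_cart_point(r, theta, phi)
  E <- diag(3)
  gradu <- matrix(0, 3, 3)
  for (i in 1:3) {
    gradu[i, ] <- (displacement_field(sol, matrix(p + h * E[i, ], 1)) -
                     displacement_field(sol, matrix(p - h * E[i, ], 1))) / (2 * h)
  }
  eps <- (gradu + t(gradu)) / 2
  structure(list(components = eps, basis = "cartesian",
                 location = c(r, theta, phi)),
            class = "strain_tensor")
}

#' Stress via Hooke's law applied to finite-difference strain
#'
#' Independent oracle: \eqn{\hat T = 2G(\frac{\nu}{1-2\nu}\mathrm{tr}(\hat\epsilon)\hat E
#' + \hat\epsilon)} with the strain from [strain_tensor()].  Used only for
#' validation of the analytic assembly.
#'
#' @param sol An `elastic_solution`.
#' @param point Length-3 Cartesian position (interior, off the interface).
#' @param h FD step.
#' @return A [stress_tensor_obj()].
#' @export
hooke_oracle_stress <- function(sol, point, h = 1e-5 * sol$r0) {
  sph <- cart_to_sph(matrix(point, 1))
  eps <- strain_tensor(sol, sph$r, sph$theta, sph$phi, h = h)$components
  G <- sol$material$G
  nu <- sol$material$nu
  Tm <- 2 * G * (nu / (1 - 2 * nu) * sum(diag(eps)) * diag(3) + eps)
  sphc <- c(sph$r, sph$theta, sph$phi)
  stress_tensor_obj(Tm, basis = "cartesian", location = sphc)
}

#' Surface map of the stress tensor in spherical components
#'
#' Evaluates the six independent spherical-basis stress components on an
#' angular grid just inside the initial sphere (`r = r0 * (1 - offset)`; the
#' two-branch field is only C0-matched at `r0` and the bead-side limit is the
#' physically reported quantity).
#'
#' @param sol An `elastic_solution`.
#' @param n_theta,n_phi Grid resolution (default 36 x 72; minimum 8 x 8).
#' @param offset Relative inward offset of the evaluation radius (default 1e-6).
#' @return Data frame with columns `theta`, `phi` (radians), `Trr`, `Ttt`,
#'   `Tpp`, `Trt`, `Trp`, `Ttp` (Pa).
#' @export
surface_stress_map <- function(sol, n_theta = 36, n_phi = 72, offset = 1e-6) {
  stopifnot(n_theta >= 8, n_phi >= 8)
  r <- sol$r0 * (1 - offset)
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  grid <- expand.grid(theta = theta, phi = phi)
  comp <- t(vapply(seq_len(nrow(grid)), function(i) {
    Ts <- spherical_components(
      stress_tensor(sol, r, grid$theta[i], grid$phi[i]))$components
    c(Ts[1, 1], Ts[2, 2], Ts[3, 3], Ts[1, 2], Ts[1, 3], Ts[2, 3])
  }, numeric(6)))
  data.frame(theta = grid$theta, phi = grid$phi,
             Trr = comp[, 1], Ttt = comp[, 2], Tpp = comp[, 3],
             Trt = comp[, 4], Trp = comp[, 5], Ttp = comp[, 6])
}
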