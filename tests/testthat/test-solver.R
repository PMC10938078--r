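# Solver module: Cartesian boundary expansion, divergence, scalar-potential
# coupling, displacement field, and the Navier-Lame residual oracle.

test_that("material guards its parameter domain", {
  m <- material(720, 0.491)
  expect_equal(m$G, 720)
  expect_error(material(-1, 0.3), "positive")
  expect_error(material(100, 0.5), "nu")
  expect_error(material(100, -1.2), "nu")
})

test_that("a uniform radial boundary maps to pure degree-1 K coefficients", {
  geom <- displacement_coeffs(make_sphere_shape(0.9), 1)   # d00 only
  K <- boundary_to_cartesian(geom)
  deg <- rep.int(0:K$N, 2 * (0:K$N) + 1)
  expect_lt(max(abs(K$K[deg != 1, ])), 1e-14)
  expect_gt(max(abs(K$K[deg == 1, ])), 0)
  # reconstructed boundary field is (d00 / sqrt(4 pi)) e_r pointwise
  th <- seq(0.1, pi - 0.1, length.out = 15)
  ph <- seq(0, 2 * pi - 0.1, length.out = 15)
  g <- expand.grid(th = th, ph = ph)
  Y <- ynm_matrix(K$N, g$th, g$ph)
  er <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  alpha <- Re(geom$dnm$coef[sh_index(0, 0)]) / sqrt(4 * pi)
  for (j in 1:3) {
    expect_equal(Re(Y %*% K$K[, j]), alpha * er[, j],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a pure quadrupole boundary produces K support on degrees 1 and 3 only", {
  geom <- displacement_coeffs(make_uniaxial_shape(1, 0.2), 1)
  K <- boundary_to_cartesian(geom)
  deg <- rep.int(0:K$N, 2 * (0:K$N) + 1)
  expect_lt(max(abs(K$K[!(deg %in% c(1, 3)), ])), 1e-14)
  expect_gt(max(abs(K$K[deg == 1, ])), 0)
  expect_gt(max(abs(K$K[deg == 3, ])), 0)
})

test_that("K reconstructs the Cartesian boundary displacement pointwise", {
  for (seed in 1:3) {
    shape <- make_random_shape(1, 4, amplitude = 0.15, seed = seed,
                               include_degree1 = TRUE)
    geom <- displacement_coeffs(shape, 1.03)
    K <- boundary_to_cartesian(geom)
    th <- seq(0.05, pi - 0.05, length.out = 20)
    ph <- seq(0, 2 * pi - 0.05, length.out = 20)
    g <- expand.grid(th = th, ph = ph)
    YK <- ynm_matrix(K$N, g$th, g$ph)
    Yd <- ynm_matrix(shape$N, g$th, g$ph)
    dval <- Re(Yd %*% geom$dnm$coef)
    er <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
    for (j in 1:3) {
      expect_lt(max(abs(Re(YK %*% K$K[, j]) - dval * er[, j])), 1e-10)
    }
    # real boundary => conjugate-symmetric K, componentwise
    for (n in 0:K$N) for (m in 0:n) {
      expect_lt(max(abs(K$K[sh_index(n, -m), ] -
                          (-1)^m * Conj(K$K[sh_index(n, m), ]))), 1e-12)
    }
  }
})

test_that("divergence coefficients: constants, the identity field, and FD", {
  # constant U (degree-0 K only): zero divergence
  Kc <- structure(list(N = 0L, K = matrix(c(1, 2, 3) + 0i, 1, 3), r0 = 1),
                  class = "vector_boundary_expansion")
  dc <- divergence_coeffs(Kc, 1)
  expect_lt(max(abs(dc$c)), 1e-14)
  # U = (x, y, z): div = 3, a single degree-0 term with c * Y00 = 3
  r0 <- 1.4
  K1 <- matrix(0 + 0i, sh_size(1), 3)
  b <- sqrt(2 * pi / 3) * r0
  K1[sh_index(1, -1), 1] <- b;      K1[sh_index(1, 1), 1] <- -b
  K1[sh_index(1, -1), 2] <- 1i * b; K1[sh_index(1, 1), 2] <- 1i * b
  K1[sh_index(1, 0), 3] <- sqrt(4 * pi / 3) * r0
  Kid <- structure(list(N = 1L, K = K1, r0 = r0),
                   class = "vector_boundary_expansion")
  dc <- divergence_coeffs(Kid, r0)
  expect_equal(Re(dc$c[sh_index(1, 0)]) / sqrt(4 * pi), 3, tolerance = 1e-12)
  # random K: expansion agrees with FD divergence of the evaluated field
  sol <- random_solution(4, seed = 31)
  dc <- divergence_coeffs(sol$K, sol$r0)
  cvec <- rep(0 + 0i, sh_size(sol$K$N - 1L))
  for (n in 1:sol$K$N) for (m in -(n - 1):(n - 1)) {
    cvec[sh_index(n - 1L, m)] <- dc$c[sh_index(n, m)]
  }
  h <- 1e-5
  pts <- random_shell_points(10, sol$r0, 0.2, 0.8, seed = 32)
  for (i in 1:10) {
    p <- pts[i, ]
    fd <- 0
    for (j in 1:3) {
      e <- diag(3)[j, ]
      fd <- fd + (potential_fields(sol, matrix(p + h * e, 1))$U[j] -
                    potential_fields(sol, matrix(p - h * e, 1))$U[j]) / (2 * h)
    }
    an <- Re(beadstress:::eval_regular_expansion(cvec, sol$K$N - 1L, matrix(p, 1)))
    expect_lt(abs(fd - an) / max(abs(an), 1e-6), 1e-6)
  }
})

test_that("scalar-potential coupling: zeros propagate and the denominator is the derived one", {
  geom <- displacement_coeffs(make_sphere_shape(1), 1)   # zero displacement
  sol <- solve_elastic(geom, material(1, 0.3))
  expect_lt(max(abs(sol$a$a)), 1e-14)
  expect_lt(max(abs(sol$K$K)), 1e-14)
  # derived coupling at n = 1, nu = 0: a_{0,m} = -c_{1,m}/2 (gauge for u, but
  # fixed by consistency of the expanded stress series)
  geom <- displacement_coeffs(make_sphere_shape(0.9), 1)
  K <- boundary_to_cartesian(geom)
  cdiv <- divergence_coeffs(K, 1)
  a <- psi_coeffs(cdiv, 0, 1)
  expect_equal(a$a[sh_index(0, 0)], -cdiv$c[sh_index(1, 0)] / 2,
               tolerance = 1e-12)
  # degree-0 psi coefficients are gauge: they do not move the displacement
  sol <- solve_elastic(geom, material(1, 0.25))
  sol2 <- sol
  sol2$a$a[sh_index(0, 0)] <- sol$a$a[sh_index(0, 0)] + 5
  pts <- random_shell_points(5, 1, 0.2, 0.8, seed = 33)
  expect_equal(displacement_field(sol2, pts), displacement_field(sol, pts),
               tolerance = 1e-12)
})

test_that("solve is linear in the boundary displacement", {
  shape <- make_random_shape(1, 3, amplitude = 0.1, seed = 35)
  geom <- displacement_coeffs(shape, 1.02)
  lam <- 2.7
  geom2 <- geom
  geom2$dnm <- sh_expansion(geom$dnm$N, lam * geom$dnm$coef)
  mat <- material(3, 0.4)
  s1 <- solve_elastic(geom, mat)
  s2 <- solve_elastic(geom2, mat)
  expect_equal(s2$K$K, lam * s1$K$K, tolerance = 1e-12)
  expect_equal(s2$a$a, lam * s1$a$a, tolerance = 1e-12)
  pts <- random_shell_points(6, 1.02, 0.1, 0.9, seed = 36)
  expect_equal(displacement_field(s2, pts), lam * displacement_field(s1, pts),
               tolerance = 1e-10)
})

test_that("displacement equals the boundary condition at r0 and decays at infinity", {
  sol <- random_solution(5, seed = 40, r0 = 1.2)
  th <- seq(0.05, pi - 0.05, length.out = 18)
  ph <- seq(0, 2 * pi - 0.05, length.out = 18)
  g <- expand.grid(th = th, ph = ph)
  P <- sol$r0 * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  u <- displacement_field(sol, P)
  shape <- make_random_shape(1.2 * 0.98, 5, amplitude = 0.12, seed = 40)
  d <- displacement_coeffs(shape, 1.2)$dnm$coef
  dval <- Re(ynm_matrix(5, g$th, g$ph) %*% d)
  er <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  expect_lt(max(abs(u - as.numeric(dval) * er)), 1e-10 * max(abs(dval)))
  # exterior decay
  far <- displacement_field(sol, matrix(c(60, 10, 80), 1))
  expect_lt(max(abs(far)), 1e-3 * max(abs(dval)))
})

test_that("the two branches match continuously across r0", {
  sol <- random_solution(4, seed = 41)
  dirs <- matrix(stats::rnorm(9), 3, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in 1:3) {
    gaps <- vapply(c(1e-4, 1e-6, 1e-8), function(eps) {
      ui <- displacement_field(sol, matrix(dirs[i, ] * sol$r0 * (1 - eps), 1))
      uo <- displacement_field(sol, matrix(dirs[i, ] * sol$r0 * (1 + eps), 1))
      max(abs(ui - uo))
    }, numeric(1))
    expect_lt(gaps[3], 1e-7)
    expect_true(all(diff(gaps) <= 1e-7))   # shrinking gap in the eps sweep
  }
})

test_that("potentials are harmonic in both branches", {
  sol <- random_solution(4, seed = 42, include_degree1 = TRUE)
  h <- 1e-4 * sol$r0
  pts <- rbind(random_shell_points(8, sol$r0, 0.15, 0.85, seed = 43),
               random_shell_points(8, sol$r0, 1.2, 2.5, seed = 44))
  for (i in seq_len(nrow(pts))) {
    expect_lt(fd_laplacian(function(P) potential_fields(sol, P)$psi,
                           pts[i, ], h)$rel, 1e-5)
    for (j in 1:3) {
      expect_lt(fd_laplacian(function(P) potential_fields(sol, P)$U[, j],
                             pts[i, ], h)$rel, 1e-5)
    }
  }
})

test_that("a rigid translation has vanishing Navier residual", {
  # constant U, psi = 0: build via a degree-0-only boundary of the solver types
  sol <- random_solution(2, seed = 45)
  sol$K$K[] <- 0
  sol$K$K[sh_index(0, 0), ] <- c(1, -2, 0.5) * sqrt(4 * pi)
  sol$a$a[] <- 0
  res <- navier_residual(sol, c(0.2, 0.1, -0.3))
  expect_lt(res$rel, 1e-6)
})

test_that("random solutions satisfy the Navier-Lame equation; corruption is detected", {
  sol <- random_solution(4, seed = 46, nu = 0.42)
  pts <- random_shell_points(10, sol$r0, 0.15, 0.8, seed = 47)
  rels <- vapply(seq_len(nrow(pts)), function(i) {
    navier_residual(sol, pts[i, ])$rel
  }, numeric(1))
  expect_lt(max(rels), 1e-4)
  # corrupt one scalar-potential coefficient by 10%
  bad <- sol
  k <- sh_index(2, 1)
  bad$a$a[k] <- bad$a$a[k] * 1.1
  bad$a$a[sh_index(2, -1)] <- Conj(bad$a$a[k]) * (-1)
  rel_bad <- max(vapply(1:5, function(i) navier_residual(bad, pts[i, ])$rel,
                        numeric(1)))
  expect_gt(rel_bad, 100 * max(rels))
})

test_that("solving a z-rotated boundary rotates the displacement field", {
  alpha <- 0.9
  shape <- make_random_shape(1, 3, amplitude = 0.12, seed = 48)
  rshape <- shape
  for (n in 0:3) for (m in -n:n) {
    # coefficients of the +alpha-rotated surface carry the phase exp(-i m alpha)
    rshape$coef[sh_index(n, m)] <- shape$coef[sh_index(n, m)] * exp(-1i * m * alpha)
  }
  mat <- material(1, 0.3)
  s0 <- solve_elastic(displacement_coeffs(shape, 1.02), mat)
  sR <- solve_elastic(displacement_coeffs(rshape, 1.02), mat)
  Rz <- matrix(c(cos(alpha), -sin(alpha), 0, sin(alpha), cos(alpha), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  pts <- random_shell_points(6, 1.02, 0.2, 0.9, seed = 49)
  u0 <- displacement_field(s0, pts)
  uR <- displacement_field(sR, pts %*% t(Rz))
  expect_equal(uR, u0 %*% t(Rz), tolerance = 1e-9)
})

test_that("navier_residual refuses stencils across the interface", {
  sol <- random_solution(2, seed = 50)
  expect_error(navier_residual(sol, c(0, 0, sol$r0 * 0.99999)), "stencil")
})
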