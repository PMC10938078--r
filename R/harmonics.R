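# Spherical-harmonic substrate: orthonormal complex harmonics (Condon-Shortley
# phase), solid spherical harmonics, Clebsch-Gordan coefficients, product
# linearization, and the Cartesian gradient ladder for solid harmonics.
#
# Coefficient vectors index the pair (n, m), |m| <= n <= N, through
# sh_index(n, m) = n^2 + n + m + 1, so a degree-N expansion has (N+1)^2 slots.

#' Linear index of a spherical-harmonic coefficient
#'
#' Maps degree/order pairs to positions in the flat coefficient vectors used
#' throughout the package: `sh_index(n, m) = n^2 + n + m + 1`.
#'
#' @param n Integer degree(s), `n >= 0`.
#' @param m Integer order(s), `-n <= m <= n`.
#' @return Integer index (1-based).
#' @export
sh_index <- function(n, m) {
  stopifnot(all(n >= 0), all(abs(m) <= n))
  as.integer(n * n + n + m + 1)
}

#' Number of coefficients in a degree-N expansion
#' @param N Truncation degree.
#' @return `(N+1)^2`.
#' @export
sh_size <- function(N) as.integer((N + 1)^2)

# degree n of every slot in a length-(N+1)^2 coefficient vector
sh_degree_of_slot <- function(N) {
  rep.int(0:N, times = 2 * (0:N) + 1)
}

# order m of every slot
sh_order_of_slot <- function(N) {
  unlist(lapply(0:N, function(n) -n:n), use.names = FALSE)
}

#' Matrix of orthonormal spherical harmonics
#'
#' Evaluates every \eqn{Y_{nm}} with \eqn{n \le N} at the given angles using a
#' fully normalized, stable three-term recurrence (normalization folded into
#' the recurrence so degrees up to a few hundred are safe).  The convention is
#' the orthonormal complex one with Condon-Shortley phase:
#' \eqn{\oint Y_{nm} Y_{n'm'}^* d\Omega = \delta_{nn'}\delta_{mm'}} and
#' \eqn{Y_{n,-m} = (-1)^m Y_{nm}^*}.
#'
#' @param N Maximum degree.
#' @param theta Polar angles in radians, in `[0, pi]`.
#' @param phi Azimuthal angles in radians.
#' @return Complex matrix, `length(theta)` rows, `(N+1)^2` columns indexed by
#'   [sh_index()].
#' @export
ynm_matrix <- function(N, theta, phi) {
  stopifnot(N >= 0, length(theta) == length(phi))
  x <- cos(theta)
  sx <- sin(theta)
  npt <- length(theta)
  out <- matrix(0 + 0i, npt, sh_size(N))
  pm_prev <- NULL
  for (m in 0:N) {
    pmm <- if (m == 0) rep(sqrt(1 / (4 * pi)), npt) else {
      -sqrt((2 * m + 1) / (2 * m)) * sx * pm_prev
    }
    pm_prev <- pmm
    em <- exp(1i * m * phi)
    out[, sh_index(m, m)] <- pmm * em
    if (m > 0) out[, sh_index(m, -m)] <- (-1)^m * pmm * Conj(em)
    if (m < N) {
      pn2 <- pmm
      pn1 <- sqrt(2 * m + 3) * x * pmm
      out[, sh_index(m + 1L, m)] <- pn1 * em
      if (m > 0) out[, sh_index(m + 1L, -m)] <- (-1)^m * pn1 * Conj(em)
      if (m + 2L <= N) {
        for (n in (m + 2L):N) {
          a <- sqrt((2 * n - 1) * (2 * n + 1) / ((n - m) * (n + m)))
          b <- sqrt((2 * n + 1) * (n + m - 1) * (n - m - 1) /
                      ((n - m) * (n + m) * (2 * n - 3)))
          pn <- a * x * pn1 - b * pn2
          pn2 <- pn1
          pn1 <- pn
          out[, sh_index(n, m)] <- pn * em
          if (m > 0) out[, sh_index(n, -m)] <- (-1)^m * pn * Conj(em)
        }
      }
    }
  }
  out
}

#' Evaluate a single orthonormal spherical harmonic
#'
#' @param n Degree. @param m Order, `|m| <= n`.
#' @param theta,phi Angles in radians (vectorized, recycled to common length).
#' @return Complex vector of \eqn{Y_{nm}(\theta, \phi)}.
#' @export
eval_ynm <- function(n, m, theta, phi) {
  if (abs(m) > n) stop("eval_ynm: |m| must not exceed n (got n=", n, ", m=", m, ")")
  k <- max(length(theta), length(phi))
  theta <- rep_len(theta, k)
  phi <- rep_len(phi, k)
  ynm_matrix(n, theta, phi)[, sh_index(n, m)]
}

# spherical coordinates of Cartesian points (k x 3 matrix); r = 0 maps to the
# north pole so that r^n Y_nm is still evaluated correctly (only n = 0 survives)
cart_to_sph <- function(points) {
  points <- as_points(points)
  r <- sqrt(rowSums(points^2))
  ct <- ifelse(r > 0, pmin(1, pmax(-1, points[, 3] / r)), 1)
  list(r = r, theta = acos(ct), phi = atan2(points[, 2], points[, 1]))
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}

#' Regular solid spherical harmonic \eqn{R_{nm} = r^n Y_{nm}}
#'
#' @param n Degree. @param m Order.
#' @param points Cartesian positions, numeric vector of length 3 or a k x 3 matrix.
#' @return Complex vector.
#' @export
eval_regular_ssh <- function(n, m, points) {
  if (abs(m) > n) stop("eval_regular_ssh: |m| > n")
  points <- as_points(points)
  s <- cart_to_sph(points)
  rn <- ifelse(s$r == 0, as.numeric(n == 0), s$r^n)
  rn * ynm_matrix(n, s$theta, s$phi)[, sh_index(n, m)]
}

#' Irregular solid spherical harmonic \eqn{I_{nm} = Y_{nm} / r^{n+1}}
#'
#' @inheritParams eval_regular_ssh
#' @return Complex vector; errors at the origin (singular point).
#' @export
eval_irregular_ssh <- function(n, m, points) {
  if (abs(m) > n) stop("eval_irregular_ssh: |m| > n")
  points <- as_points(points)
  s <- cart_to_sph(points)
  if (any(s$r == 0)) stop("eval_irregular_ssh: singular at the origin (r = 0)")
  ynm_matrix(n, s$theta, s$phi)[, sh_index(n, m)] / s$r^(n + 1)
}

#' Clebsch-Gordan coefficient
#'
#' Computes \eqn{\langle l_1 m_1; l_2 m_2 | L M \rangle} for integer angular
#' momenta from Racah's closed-form sum.  Factorials are taken as
#' double-precision products (exact integers through 18!); for the moderate
#' degrees used here the few-term sum has negligible cancellation.  Invalid
#' couplings (violated triangle rule, \eqn{M \neq m_1 + m_2}) return 0.
#'
#' @param l1,m1,l2,m2,L,M Integer quantum numbers.
#' @return Numeric scalar.
#' @export
clebsch_gordan <- function(l1, m1, l2, m2, L, M) {
  stopifnot(l1 >= 0, l2 >= 0, L >= 0,
            l1 == round(l1), l2 == round(l2), L == round(L),
            m1 == round(m1), m2 == round(m2), M == round(M))
  if (abs(m1) > l1 || abs(m2) > l2 || abs(M) > L) return(0)
  if (M != m1 + m2) return(0)
  if (L < abs(l1 - l2) || L > l1 + l2) return(0)
  f <- factorial
  delta <- sqrt(f(l1 + l2 - L) * f(l1 - l2 + L) * f(-l1 + l2 + L) /
                  f(l1 + l2 + L + 1))
  pre <- sqrt((2 * L + 1) * f(L + M) * f(L - M) *
                f(l1 + m1) * f(l1 - m1) * f(l2 + m2) * f(l2 - m2))
  zmin <- max(0, l2 - L - m1, l1 - L + m2)
  zmax <- min(l1 + l2 - L, l1 - m1, l2 + m2)
  s <- 0
  for (z in zmin:zmax) {
    s <- s + (-1)^z / (f(z) * f(l1 + l2 - L - z) * f(l1 - m1 - z) *
                         f(l2 + m2 - z) * f(L - l2 + m1 + z) * f(L - l1 - m2 + z))
  }
  delta * pre * s
}

#' Linearize a product of two spherical harmonics
#'
#' Expands \eqn{Y_{l_1 m_1} Y_{l_2 m_2}} as a finite sum of single harmonics
#' \eqn{Y_{LM}} with \eqn{M = m_1 + m_2} and
#' \eqn{L \in \{|l_1-l_2|, \dots, l_1+l_2\}}:
#' \deqn{Y_{l_1 m_1} Y_{l_2 m_2} = \sum_L
#'   \sqrt{\frac{(2l_1+1)(2l_2+1)}{4\pi(2L+1)}}\,
#'   \langle l_1 0 l_2 0|L 0\rangle \langle l_1 m_1 l_2 m_2|L M\rangle\, Y_{LM}.}
#'
#' @param l1,m1,l2,m2 Integer indices of the two factors.
#' @return Data frame with columns `L`, `M`, `coef` (nonzero terms only).
#' @export
linearize_sh_product <- function(l1, m1, l2, m2) {
  stopifnot(abs(m1) <= l1, abs(m2) <= l2)
  M <- m1 + m2
  Ls <- abs(l1 - l2):(l1 + l2)
  Ls <- Ls[abs(M) <= Ls]
  coef <- vapply(Ls, function(L) {
    sqrt((2 * l1 + 1) * (2 * l2 + 1) / (4 * pi * (2 * L + 1))) *
      clebsch_gordan(l1, 0, l2, 0, L, 0) *
      clebsch_gordan(l1, m1, l2, m2, L, M)
  }, numeric(1))
  keep <- coef != 0
  data.frame(L = Ls[keep], M = rep(M, sum(keep)), coef = coef[keep])
}

# ---- Cartesian gradient ladders for solid harmonics -------------------------
#
# Gradients of solid harmonics are solid harmonics one degree lower (regular)
# or one degree higher (irregular).  With ladder operators d+/- = dx +/- i dy:
#   regular R_nm = r^n Y_nm:
#     dz R_nm = sqrt((n-m)(n+m)(2n+1)/(2n-1))           R_{n-1,m}
#     d+ R_nm = sqrt((n-m)(n-m-1)(2n+1)/(2n-1))         R_{n-1,m+1}
#     d- R_nm = -sqrt((n+m)(n+m-1)(2n+1)/(2n-1))        R_{n-1,m-1}
#   irregular I_nm = Y_nm / r^{n+1}:
#     dz I_nm = -sqrt((n-m+1)(n+m+1)(2n+1)/(2n+3))      I_{n+1,m}
#     d+ I_nm =  sqrt((n+m+1)(n+m+2)(2n+1)/(2n+3))      I_{n+1,m+1}
#     d- I_nm = -sqrt((n-m+1)(n-m+2)(2n+1)/(2n+3))      I_{n+1,m-1}
# All six are exercised by finite-difference tests.

#' Cartesian gradient of a regular solid harmonic
#'
#' Returns the exact degree-lowering expansion of
#' \eqn{(\partial_x, \partial_y, \partial_z)\, r^n Y_{nm}} in regular solid
#' harmonics of degree `n - 1`.
#'
#' @param n Degree (`n >= 1`; `n = 0` yields empty expansions).
#' @param m Order.
#' @return List with elements `x`, `y`, `z`, each a data frame with columns
#'   `n`, `m`, `coef` (complex).
#' @export
cartesian_gradient_rssh <- function(n, m) {
  stopifnot(abs(m) <= n)
  empty <- data.frame(n = integer(0), m = integer(0), coef = complex(0))
  if (n == 0) return(list(x = empty, y = empty, z = empty))
  az <- sqrt((n - m) * (n + m) * (2 * n + 1) / (2 * n - 1))
  ap <- sqrt(max(0, n - m) * max(0, n - m - 1) * (2 * n + 1) / (2 * n - 1))
  am <- -sqrt(max(0, n + m) * max(0, n + m - 1) * (2 * n + 1) / (2 * n - 1))
  x <- y <- z <- empty
  if (abs(m) <= n - 1 && az != 0) {
    z <- data.frame(n = n - 1L, m = m, coef = as.complex(az))
  }
  if (abs(m + 1) <= n - 1 && ap != 0) {
    x <- rbind(x, data.frame(n = n - 1L, m = m + 1L, coef = as.complex(ap / 2)))
    y <- rbind(y, data.frame(n = n - 1L, m = m + 1L, coef = as.complex(-1i * ap / 2)))
  }
  if (abs(m - 1) <= n - 1 && am != 0) {
    x <- rbind(x, data.frame(n = n - 1L, m = m - 1L, coef = as.complex(am / 2)))
    y <- rbind(y, data.frame(n = n - 1L, m = m - 1L, coef = as.complex(1i * am / 2)))
  }
  list(x = x, y = y, z = z)
}

# gradient of a whole regular expansion (plain r^n Y_nm coefficients, flat
# vector of length (N+1)^2) -> list of three flat vectors of degree N-1
grad_regular_expansion <- function(coef, N) {
  if (N <= 0) {
    return(list(x = complex(1), y = complex(1), z = complex(1), N = 0L, zero = TRUE))
  }
  Nm1 <- N - 1L
  gx <- gy <- gz <- rep(0 + 0i, sh_size(Nm1))
  for (n in 1:N) {
    for (m in -n:n) {
      c0 <- coef[sh_index(n, m)]
      if (c0 == 0) next
      az <- sqrt((n - m) * (n + m) * (2 * n + 1) / (2 * n - 1))
      ap <- sqrt(max(0, n - m) * max(0, n - m - 1) * (2 * n + 1) / (2 * n - 1))
      am <- -sqrt(max(0, n + m) * max(0, n + m - 1) * (2 * n + 1) / (2 * n - 1))
      if (abs(m) <= n - 1 && az != 0) {
        k <- sh_index(n - 1L, m)
        gz[k] <- gz[k] + az * c0
      }
      if (abs(m + 1) <= n - 1 && ap != 0) {
        k <- sh_index(n - 1L, m + 1L)
        gx[k] <- gx[k] + ap / 2 * c0
        gy[k] <- gy[k] - 1i * ap / 2 * c0
      }
      if (abs(m - 1) <= n - 1 && am != 0) {
        k <- sh_index(n - 1L, m - 1L)
        gx[k] <- gx[k] + am / 2 * c0
        gy[k] <- gy[k] + 1i * am / 2 * c0
      }
    }
  }
  list(x = gx, y = gy, z = gz, N = Nm1, zero = FALSE)
}

# gradient of an irregular expansion (plain Y_nm / r^{n+1} coefficients,
# degree N) -> three flat vectors of degree N+1
grad_irregular_expansion <- function(coef, N) {
  Np1 <- N + 1L
  gx <- gy <- gz <- rep(0 + 0i, sh_size(Np1))
  for (n in 0:N) {
    for (m in -n:n) {
      c0 <- coef[sh_index(n, m)]
      if (c0 == 0) next
      az <- -sqrt((n - m + 1) * (n + m + 1) * (2 * n + 1) / (2 * n + 3))
      ap <- sqrt((n + m + 1) * (n + m + 2) * (2 * n + 1) / (2 * n + 3))
      am <- -sqrt((n - m + 1) * (n - m + 2) * (2 * n + 1) / (2 * n + 3))
      k <- sh_index(n + 1L, m)
      gz[k] <- gz[k] + az * c0
      k <- sh_index(n + 1L, m + 1L)
      gx[k] <- gx[k] + ap / 2 * c0
      gy[k] <- gy[k] - 1i * ap / 2 * c0
      k <- sh_index(n + 1L, m - 1L)
      gx[k] <- gx[k] + am / 2 * c0
      gy[k] <- gy[k] + 1i * am / 2 * c0
    }
  }
  list(x = gx, y = gy, z = gz, N = Np1, zero = FALSE)
}

# evaluate a plain regular solid-harmonic expansion at Cartesian points
eval_regular_expansion <- function(coef, N, points) {
  points <- as_points(points)
  s <- cart_to_sph(points)
  Y <- ynm_matrix(N, s$theta, s$phi)
  rn <- outer(s$r, 0:N, function(r, n) ifelse(r == 0, as.numeric(n == 0), r^n))
  deg <- sh_degree_of_slot(N)
  drop((Y * rn[, deg + 1, drop = FALSE]) %*% coef)
}

# evaluate a plain irregular expansion (coef of Y_nm / r^{n+1}) at points
eval_irregular_expansion <- function(coef, N, points) {
  points <- as_points(points)
  s <- cart_to_sph(points)
  if (any(s$r == 0)) stop("irregular expansion is singular at the origin")
  Y <- ynm_matrix(N, s$theta, s$phi)
  rn <- outer(s$r, 0:N, function(r, n) r^(-(n + 1)))
  deg <- sh_degree_of_slot(N)
  drop((Y * rn[, deg + 1, drop = FALSE]) %*% coef)
}

# conjugate-symmetry defect of a coefficient vector representing a real field
conjugate_symmetry_defect <- function(coef, N) {
  d <- 0
  for (n in 0:N) {
    d <- max(d, abs(Im(coef[sh_index(n, 0)])))
    if (n > 0) for (m in 1:n) {
      d <- max(d, abs(coef[sh_index(n, -m)] - (-1)^m * Conj(coef[sh_index(n, m)])))
    }
  }
  d
}
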