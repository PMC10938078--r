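# Surface module: point-cloud I/O, spherical-harmonic shape fitting, order
# selection, enclosed volume, initial radius, and the radial-displacement
# boundary coefficients.

#' Scalar spherical-harmonic expansion
#'
#' Container for an expansion \eqn{f(\theta,\phi) = \sum_{n \le N} c_{nm} Y_{nm}}
#' in the package's orthonormal complex convention.  Real-valued fields are
#' represented by complex coefficients constrained by conjugate symmetry
#' \eqn{c_{n,-m} = (-1)^m \bar c_{nm}}.
#'
#' @param N Truncation degree.
#' @param coef Complex vector of length `(N+1)^2` indexed by [sh_index()].
#' @param real Logical; if `TRUE` (default) conjugate symmetry is checked.
#' @return Object of class `sh_expansion`.
#' @export
sh_expansion <- function(N, coef, real = TRUE) {
  stopifnot(N >= 0, length(coef) == sh_size(N))
  coef <- as.complex(coef)
  if (real) {
    defect <- conjugate_symmetry_defect(coef, N)
    scale <- max(abs(coef), 1e-300)
    if (defect > 1e-8 * scale) {
      warning("coefficients deviate from conjugate symmetry by ",
              format(defect), " (expected a real-valued field)")
    }
  }
  structure(list(N = as.integer(N), coef = coef,
                 convention = "orthonormal-condon-shortley", real = real),
            class = "sh_expansion")
}

#' @export
print.sh_expansion <- function(x, ...) {
  cat("<sh_expansion> degree N =", x$N, "(", sh_size(x$N), "coefficients ),",
      "convention:", x$convention, "\n")
  invisible(x)
}

#' Evaluate the radius function of a shape expansion
#'
#' @param shape An [sh_expansion()].
#' @param theta,phi Angles in radians (equal length).
#' @return Numeric vector \eqn{s(\theta, \phi)}; a warning is thrown if the
#'   imaginary residual of the assembled field is non-negligible.
#' @export
radius_function <- function(shape, theta, phi) {
  v <- drop(ynm_matrix(shape$N, theta, phi) %*% shape$coef)
  if (max(abs(Im(v))) > 1e-8 * max(abs(v), 1e-300)) {
    warning("radius function has non-negligible imaginary part")
  }
  Re(v)
}

#' Point cloud of a bead surface
#'
#' @param points Numeric k x 3 matrix of Cartesian positions (length units of
#'   the microscope, e.g. micrometres).
#' @param center Origin for the radial parameterization; defaults to the
#'   centroid of the points.
#' @return Object of class `point_cloud`.
#' @export
point_cloud <- function(points, center = NULL) {
  points <- as_points(points)
  if (nrow(points) < 4) stop("point cloud needs at least 4 points")
  if (is.null(center)) center <- colMeans(points)
  stopifnot(length(center) == 3)
  rel <- sweep(points, 2, center)
  r <- sqrt(rowSums(rel^2))
  if (any(r <= 0)) stop("all points must lie strictly away from the center")
  structure(list(points = points, center = as.numeric(center)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("<point_cloud>", nrow(x$points), "points, center =",
      paste(signif(x$center, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Read a surface point cloud from disk
#'
#' CSV files must contain one `x,y,z` row per point (an optional header line is
#' detected automatically).  PLY files must be ASCII; only the vertex element
#' is read.
#'
#' @param path File path.
#' @param format `"csv"` or `"ply"`; default guesses from the file extension.
#' @param center Optional origin (defaults to the centroid).
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "csv", "ply"),
                             center = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "csv"
  }
  pts <- if (format == "csv") read_xyz_csv(path) else read_ascii_ply(path)
  point_cloud(pts, center = center)
}

read_xyz_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty CSV file: ", path)
  first <- strsplit(lines[[1]], ",")[[1]]
  start <- if (suppressWarnings(any(is.na(as.numeric(first))))) 2L else 1L
  if (start > length(lines)) stop("CSV contains a header but no data rows")
  rows <- lapply(start:length(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(lines[[i]], ",")[[1]]))
    if (length(f) != 3 || any(is.na(f))) {
      stop("malformed CSV row at line ", i, ": expected three numeric fields, got '",
           lines[[i]], "'")
    }
    f
  })
  do.call(rbind, rows)
}

# minimal ASCII-PLY reader (vertex x/y/z properties only); no binary support
read_ascii_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[[1]]) != "ply") {
    stop("not a PLY file: ", path)
  }
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  vline <- grep("^element vertex ", hdr, value = TRUE)
  if (length(vline) != 1) stop("PLY file must declare one vertex element")
  nvert <- as.integer(strsplit(vline, "\\s+")[[1]][3])
  # property order within the vertex element
  el_lines <- grep("^element ", hdr)
  vstart <- grep("^element vertex ", hdr)
  vend <- c(el_lines[el_lines > vstart], hdr_end)[1] - 1L
  props <- sub("^property \\S+ ", "", grep("^property ", hdr[vstart:vend], value = TRUE))
  ixyz <- match(c("x", "y", "z"), props)
  if (any(is.na(ixyz))) stop("PLY vertex element lacks x/y/z properties")
  body <- lines[(hdr_end + 1):(hdr_end + nvert)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m[, ixyz, drop = FALSE]
}

# real re-parameterization of a conjugate-symmetric expansion: basis columns
# are Y_n0, 2*Re(Y_nm), -2*Im(Y_nm) (m > 0); returns the real design matrix
real_sh_design <- function(N, theta, phi) {
  Y <- ynm_matrix(N, theta, phi)
  B <- matrix(0, length(theta), sh_size(N))
  for (n in 0:N) {
    B[, sh_index(n, 0)] <- Re(Y[, sh_index(n, 0)])
    if (n > 0) for (m in 1:n) {
      B[, sh_index(n, m)] <- 2 * Re(Y[, sh_index(n, m)])
      B[, sh_index(n, -m)] <- -2 * Im(Y[, sh_index(n, m)])
    }
  }
  B
}

# real parameter vector -> complex conjugate-symmetric coefficients
real_params_to_complex <- function(par, N) {
  coef <- rep(0 + 0i, sh_size(N))
  for (n in 0:N) {
    coef[sh_index(n, 0)] <- par[sh_index(n, 0)]
    if (n > 0) for (m in 1:n) {
      c0 <- complex(real = par[sh_index(n, m)], imaginary = par[sh_index(n, -m)])
      coef[sh_index(n, m)] <- c0
      coef[sh_index(n, -m)] <- (-1)^m * Conj(c0)
    }
  }
  coef
}

#' Fit a spherical-harmonic expansion to surface points
#'
#' Converts the points to spherical coordinates about the cloud center and
#' solves the linear least-squares problem
#' \eqn{\min \sum_i | \sum_{nm} s_{nm} Y_{nm}(\theta_i,\phi_i) - r_i |^2}
#' under the conjugate-symmetry constraint (via a real re-parameterization).
#'
#' @param cloud A [point_cloud()].
#' @param N Truncation degree; requires `(N+1)^2 <=` number of points.
#' @param ridge Optional Tikhonov penalty (default 0) for ill-conditioned
#'   angular sampling.
#' @return An [sh_expansion()] with attributes `residuals` (per-point radius
#'   residuals), `rms_residual`, `max_residual` and `condition` (design-matrix
#'   condition number estimate).
#' @export
fit_shape <- function(cloud, N, ridge = 0) {
  stopifnot(inherits(cloud, "point_cloud"), N >= 0)
  rel <- sweep(cloud$points, 2, cloud$center)
  s <- cart_to_sph(rel)
  npts <- length(s$r)
  if (sh_size(N) > npts) {
    stop("underdetermined fit: degree ", N, " needs (N+1)^2 = ", sh_size(N),
         " points but only ", npts, " are available")
  }
  B <- real_sh_design(N, s$theta, s$phi)
  if (ridge > 0) {
    A <- crossprod(B) + diag(ridge, ncol(B))
    par <- solve(A, crossprod(B, s$r))
  } else {
    qrB <- qr(B)
    if (qrB$rank < ncol(B)) {
      kappa_est <- kappa(B, exact = FALSE)
      stop("rank-deficient spherical-harmonic design (clustered angles); ",
           "rank ", qrB$rank, " < ", ncol(B),
           ", condition number ~ ", format(kappa_est, digits = 3))
    }
    par <- qr.coef(qrB, s$r)
  }
  coef <- real_params_to_complex(drop(par), N)
  fit <- Re(B %*% par)
  resid <- s$r - fit
  out <- sh_expansion(N, coef, real = TRUE)
  attr(out, "residuals") <- as.numeric(resid)
  attr(out, "rms_residual") <- sqrt(mean(resid^2))
  attr(out, "max_residual") <- max(abs(resid))
  attr(out, "condition") <- kappa(B, exact = FALSE)
  out
}

#' Automatic truncation-order selection
#'
#' Fits expansions of increasing degree and locates the smallest degree
#' \eqn{n^*} at which the maximum pointwise residual falls below `exact_tol`
#' (the fit "coincides with the data points" within tolerance).  If that
#' happens while the parameter count is still far below the number of points
#' (`(n*+1)^2 <= band_limit_frac * npoints`) the data are genuinely
#' band-limited and `nmax = n*`; otherwise the interpolation regime was reached
#' by overfitting noise and the expansion is truncated at `nmax = floor(n*/2)`.
#'
#' @param cloud A [point_cloud()].
#' @param exact_tol Residual tolerance; default `1e-3 * median(r_i)`.
#' @param band_limit_frac Fraction of the point count below which an exact fit
#'   is attributed to band-limited data rather than interpolation (default 0.5).
#' @return Integer `nmax` with attributes `n_star` (degree at which the
#'   residual condition was met) and `reached` (FALSE if the interpolation
#'   regime was never reached before the point-count limit; the largest
#'   admissible degree is then returned with a warning).
#' @export
select_order <- function(cloud, exact_tol = NULL, band_limit_frac = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"))
  rel <- sweep(cloud$points, 2, cloud$center)
  r <- sqrt(rowSums(rel^2))
  npts <- length(r)
  if (is.null(exact_tol)) exact_tol <- 1e-3 * stats::median(r)
  n_limit <- floor(sqrt(npts)) - 1L   # largest degree with (N+1)^2 <= npts
  if (n_limit < 2) stop("not enough points to select an order (need >= 9)")
  n_star <- NA_integer_
  for (n in 0:n_limit) {
    fit <- fit_shape(cloud, n)
    if (attr(fit, "max_residual") < exact_tol) {
      n_star <- n
      break
    }
  }
  if (is.na(n_star)) {
    warning("interpolation regime not reached before the point-count limit; ",
            "returning the largest admissible degree ", n_limit)
    out <- n_limit
    attr(out, "n_star") <- n_limit
    attr(out, "reached") <- FALSE
    return(out)
  }
  band_limited <- sh_size(n_star) <= band_limit_frac * npts
  out <- if (band_limited) n_star else as.integer(floor(n_star / 2))
  attr(out, "n_star") <- n_star
  attr(out, "reached") <- TRUE
  out
}

# Gauss-Legendre x uniform-phi quadrature grid with polynomial exactness for
# spherical-harmonic integrands up to combined degree `deg`
sphere_quadrature <- function(deg) {
  ntheta <- max(16L, ceiling((deg + 1) / 2) + 2L)
  nphi <- max(32L, deg + 2L)
  gl <- pracma::gaussLegendre(ntheta, -1, 1)
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  grid <- expand.grid(x = gl$x, phi = phi)
  list(theta = acos(grid$x), phi = grid$phi,
       w = rep(gl$w, nphi) * (2 * pi / nphi))
}

#' Volume enclosed by a star-shaped surface
#'
#' \eqn{V = \frac{1}{3}\oint s(\theta,\phi)^3 d\Omega}, evaluated by
#' Gauss-Legendre (in \eqn{\cos\theta}) times uniform-\eqn{\phi} quadrature
#' sized for exactness at three times the expansion degree.
#'
#' @param shape An [sh_expansion()] of the radius function.
#' @return Volume (length^3).
#' @export
enclosed_volume <- function(shape) {
  q <- sphere_quadrature(3 * shape$N + 1)
  s <- radius_function(shape, q$theta, q$phi)
  if (any(s <= 0)) {
    stop("radius function is non-positive on the quadrature grid; ",
         "the surface is not star-shaped about the chosen center")
  }
  sum(q$w * s^3) / 3
}

#' Radius of the volume-equivalent sphere
#'
#' @param volume Enclosed volume.
#' @return \eqn{r_0 = (3V / 4\pi)^{1/3}}.
#' @export
initial_radius <- function(volume) {
  stopifnot(volume > 0)
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Bead geometry: initial radius plus radial-displacement coefficients
#'
#' Builds the boundary-displacement expansion from a fitted shape and the
#' initial sphere radius.  With the default `"as-printed"` sign convention the
#' surface displacement is \eqn{u|_{r_0} = (r_0 - s)\hat e_r}, i.e.
#' \eqn{d_{00} = \sqrt{4\pi}\, r_0 - s_{00}} and \eqn{d_{nm} = -s_{nm}} for
#' \eqn{n \ge 1}.  `"flipped"` uses the initial-to-deformed displacement
#' \eqn{(s - r_0)\hat e_r} instead (all coefficients negated).  A warning is
#' issued when the maximum displacement exceeds `0.3 * r0`, the rough validity
#' edge of linear elasticity.
#'
#' @param shape An [sh_expansion()] of the deformed radius.
#' @param r0 Initial sphere radius.
#' @param displacement_sign `"as-printed"` (default) or `"flipped"`.
#' @return Object of class `bead_geometry` with fields `r0` and `dnm`.
#' @export
displacement_coeffs <- function(shape, r0,
                                displacement_sign = c("as-printed", "flipped")) {
  displacement_sign <- match.arg(displacement_sign)
  stopifnot(inherits(shape, "sh_expansion"), r0 > 0)
  d <- -shape$coef
  d[sh_index(0, 0)] <- sqrt(4 * pi) * r0 - shape$coef[sh_index(0, 0)]
  if (displacement_sign == "flipped") d <- -d
  dnm <- sh_expansion(shape$N, d, real = TRUE)
  q <- sphere_quadrature(2 * shape$N + 1)
  dmax <- max(abs(Re(ynm_matrix(shape$N, q$theta, q$phi) %*% d)))
  if (dmax > 0.3 * r0) {
    warning("maximum radial displacement ", format(dmax, digits = 3),
            " exceeds 0.3 * r0 = ", format(0.3 * r0, digits = 3),
            "; linear elasticity may be inaccurate")
  }
  structure(list(r0 = r0, dnm = dnm, displacement_sign = displacement_sign,
                 max_displacement = dmax),
            class = "bead_geometry")
}

#' @export
print.bead_geometry <- function(x, ...) {
  cat("<bead_geometry> r0 =", signif(x$r0, 6), ", boundary degree N =",
      x$dnm$N, ", sign:", x$displacement_sign, "\n")
  invisible(x)
}

#' Re-center a point cloud on its volume-consistent centroid
#'
#' Iteratively shifts the expansion origin until the fitted degree-1 shape
#' coefficients (which mix rigid translation into the radial displacement)
#' vanish.  Off by default in the pipeline: the method as published does not
#' remove translation modes, but data with arbitrary segmentation origins
#' should be recentered.
#'
#' @param cloud A [point_cloud()].
#' @param N Fit degree used during the iteration (default 4).
#' @param tol Convergence tolerance on the degree-1 coefficients, relative to
#'   the mean radius (default 1e-10).
#' @param max_iter Maximum iterations (default 20).
#' @return A [point_cloud()] with updated `center`; attribute `shift` holds the
#'   total translation applied, attribute `converged` the convergence flag.
#' @export
recenter <- function(cloud, N = 4, tol = 1e-10, max_iter = 20) {
  stopifnot(inherits(cloud, "point_cloud"))
  center <- cloud$center
  npts <- nrow(cloud$points)
  N <- min(N, floor(sqrt(npts)) - 1L)
  if (N < 1) stop("too few points to estimate translation modes")
  rbar <- mean(sqrt(rowSums(sweep(cloud$points, 2, center)^2)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cl <- point_cloud(cloud$points, center = center)
    fit <- fit_shape(cl, N)
    s1m <- fit$coef[sh_index(1, -1)]
    s10 <- Re(fit$coef[sh_index(1, 0)])
    # degree-1 content of a small translation t:  s_{1,-1} = sqrt(2*pi/3) (t_x + i t_y),
    # s_{1,0} = sqrt(4*pi/3) t_z
    t <- c(Re(s1m) / sqrt(2 * pi / 3), Im(s1m) / sqrt(2 * pi / 3),
           s10 / sqrt(4 * pi / 3))
    if (sqrt(sum(t^2)) < tol * rbar) {
      converged <- TRUE
      break
    }
    center <- center + t
  }
  if (!converged) warning("recenter did not converge in ", max_iter,
                          " iterations; returning best iterate")
  out <- point_cloud(cloud$points, center = center)
  attr(out, "shift") <- center - cloud$center
  attr(out, "converged") <- converged
  out
}
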