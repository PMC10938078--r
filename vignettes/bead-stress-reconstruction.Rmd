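---
title: "Reconstructing tissue stress from bead deformation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tissue stress from bead deformation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadstress)
```

## The measurement problem

Cells sense and exert mechanical forces through the extracellular matrix, and
measuring those forces *in situ* is hard: the stresses are small (pN–nN scale
forces) and the measurement must not disturb the tissue.  A widely used
strategy embeds soft spherical sensors — polyacrylamide (PAA) hydrogel
microbeads with known shear modulus $G$ and Poisson's ratio $\nu$ — into the
tissue.  The tissue stress deforms each bead; microscopy yields a point cloud
on the deformed surface; and the inverse problem is to recover the full stress
tensor $\hat T$ from that shape.  `beadstress` implements an analytical
solution of this inverse problem for arbitrary radial deformations of a
star-shaped surface, with per-bead runtimes of seconds.

Because PAA is inert and cells cannot bind it, forces on the bead act normal
to its surface, which motivates the central modeling assumption: the surface
displacement is purely radial.  This also resolves the intrinsic
non-uniqueness of the displacement given only the deformed shape.  Shear
attachment (non-radial displacement) is outside the model's scope.

## Model

### Linear elasticity and the governing equation

Within linear elasticity ($|\partial u_i / \partial x_j| \ll 1$), Hooke's law
for an isotropic body,
$$\hat T = 2G\Big(\frac{\nu}{1-2\nu}\,\mathrm{tr}(\hat\epsilon)\,\hat E + \hat\epsilon\Big),
\qquad \hat\epsilon = \tfrac12\big(\nabla u + (\nabla u)^T\big),$$
combined with static equilibrium and negligible body forces gives the
Navier–Lamé equation for the displacement field $u$:
$$\frac{1}{1-2\nu}\,\nabla(\nabla\cdot u) + \nabla^2 u = 0 .$$

### The Love/Trefftz ansatz in solid spherical harmonics

For a body that is initially a sphere of radius $r_0$, a convenient solution
representation is
$$u = U + (r^2 - r_0^2)\,\nabla\psi ,$$
with $\psi$ and every *Cartesian* component of $U$ harmonic.  Harmonic
functions expand in solid spherical harmonics (SSH): regular
$R_{nm} = r^n Y_{nm}$ inside the sphere, irregular $I_{nm} = Y_{nm}/r^{n+1}$
outside, with matched prefactors $(r/r_0)^n$ and $(r_0/r)^{n+1}$ so each term
is continuous at $r_0$.  The package uses orthonormal complex spherical
harmonics with the Condon–Shortley phase throughout; real fields are complex
coefficient sets constrained by the conjugate symmetry
$c_{n,-m} = (-1)^m \bar c_{nm}$.  This convention is forced by the use of
Clebsch–Gordan coefficients and by the expansion of the radial unit vector
(below); real-basis harmonics would make both machinery pieces awkward.

Substituting the ansatz into the Navier–Lamé equation and matching
homogeneous degrees (Euler's theorem on homogeneous polynomials) couples the
degree-$(n-1)$ part of $\psi$ to the degree-$n$ part of $\nabla\cdot U$:
$$\psi_{n-1} = \frac{(\nabla\cdot U)_n}{2\,\big(2\nu(2n-1) - 3n + 2\big)} .$$
We derived this coupling from scratch rather than transcribing it, because
different printed variants of the denominator circulate; the package's
finite-difference Navier oracle (`navier_residual()`) discriminates sharply —
the derived form sits at the FD truncation floor ($\sim 10^{-7}$ relative)
while the common misprint with $-3n$ in place of $-3n+2$ produces order-one
residuals.  The denominator is nonzero for every $n \ge 1$ whenever
$\nu < 1/2$, which is why `material()` rejects $\nu = 1/2$ exactly.

Degree-0 terms of $\psi$ are constants inside the bead — pure gauge for the
displacement — but they are retained because the expanded stress series
(below) uses them in its bookkeeping.  In the exterior branch the degree-0
term is continued by zero: its irregular continuation $Y_{00}/r$ is *not*
constant, and keeping it would leave $(r^2-r_0^2)\nabla\psi$ of order one at
infinity instead of decaying.

### From the deformed shape to the boundary condition

The deformed radius $s(\theta,\phi)$ is expanded as
$s = \sum_{n\le N} s_{nm} Y_{nm}$.  The radial-displacement boundary
condition on the initial sphere is
$$u|_{r_0} = (r_0 - s)\,\hat e_r = \sum_{n,m} d_{nm} Y_{nm}\, \hat e_r,
\qquad d_{00} = \sqrt{4\pi}\,r_0 - s_{00},\quad d_{nm} = -s_{nm}\ (n\ge1).$$
Note the direction of this convention: it is the *deformed-to-initial*
displacement, which points inward where the bead bulges outward.  It is kept
as the package default (`displacement_sign = "as-printed"`) for consistency
with the published formulation this package follows; the physically more
natural initial-to-deformed field $(s-r_0)\hat e_r$ is available as
`displacement_sign = "flipped"` and simply negates displacement, strain and
stress.  Users comparing signs against other software should check this flag
first.

The ansatz requires the boundary field in *Cartesian* components.  The radial
unit vector is itself a degree-1 harmonic object,
$$\hat e_r = \sqrt{\tfrac{2\pi}{3}}\,
\big(Y_{1,-1} - Y_{1,1},\ i(Y_{1,-1} + Y_{1,1}),\ \sqrt2\, Y_{1,0}\big),$$
(the scalar prefactor is fixed by the trigonometric identity
$\hat e_r = (\sin\theta\cos\phi, \sin\theta\sin\phi, \cos\theta)$, which the
tests verify pointwise), so each Cartesian component of $u|_{r_0}$ is a sum
of products $Y_{nm} Y_{1\mu}$.  These are linearized with the Clebsch–Gordan
product rule
$$Y_{l_1 m_1} Y_{l_2 m_2} = \sum_{L}
\sqrt{\frac{(2l_1+1)(2l_2+1)}{4\pi(2L+1)}}\,
\langle l_1 0\, l_2 0 | L 0\rangle \langle l_1 m_1\, l_2 m_2 | L M\rangle\,
Y_{LM},$$
and the degree-$L$ content of each component is collected into vector
coefficients $K_{LM}$ (so $K$ extends one degree past the boundary
expansion).  The divergence of $U$ then follows from the exact
degree-lowering gradient ladder for solid harmonics
(`cartesian_gradient_rssh()`), and the coupling above yields the $a_{nm}$
defining $\psi$.  Every step is linear, so the whole map
$d \mapsto u \mapsto \hat T$ is linear in the boundary displacement — a
property the tests exercise directly.

### Stress assembly

The direct (reference) route evaluates
$$\hat T = 2G\Big(\frac{\nu}{1-2\nu}(\nabla\cdot U + 2\,r\cdot\nabla\psi)\hat E
+ \mathrm{Def}(U) + r\otimes\nabla\psi + (r\otimes\nabla\psi)^T
+ (r^2-r_0^2)\,\nabla\otimes\nabla\psi\Big)$$
term by term from the solid-harmonic expansions (`stress_tensor()`).  A
second, per-harmonic series route (`stress_tensor_expanded()`) applies two
exact simplifications: $r\cdot\nabla$ acts on a degree-$n$ solid harmonic as
multiplication by $n$, and the coupling denominator cancels the
$\nu/(1-2\nu)$ fraction, collapsing the isotropic term to
$-2\nu\sum_{nm}(2n+1)\,a_{nm}(r/r_0)^n Y_{nm}\hat E$.  Because published
series forms of this tensor are easy to mis-transcribe, the package treats
the direct route as the reference and gates the series route by equivalence
tests (agreement to $10^{-8}$ relative on random solutions), with an
independent finite-difference Hooke-law oracle (`hooke_oracle_stress()`,
agreement to $10^{-4}$) standing outside both analytic routes.

Exterior stress is deliberately not provided: outside the bead the material
is tissue with different and unknown moduli, so only the displacement field
is continued there.  Surface maps evaluate just inside the interface
(`r = r0*(1 - 1e-6)`), since the two-branch field is only $C^0$-matched at
$r_0$ and the bead-side limit is the physically reported quantity.

### Special cases

*Uniform deformation to radius $r_1$.*  The pipeline yields an isotropic
tensor with scalar
$$T = \frac{2G(1+\nu)}{1-2\nu}\,\frac{r_0-r_1}{r_0}$$
under the default displacement sign.  A widely quoted $8\pi G$ variant of
this prefactor presumes an unnormalized constant harmonic and differs by
exactly $4\pi$; `isotropic_sphere_stress()` implements the form above, which
is calibrated to agree with the full pipeline to $10^{-10}$ (one of the
acceptance checks).  With $G = 720$ Pa, $\nu = 0.491$ (the measured PAA bead
values) and a 5% radius reduction this gives $\approx 5964$ Pa.

*Uniaxial quadrupole* $s = \sqrt{4\pi}\,r_0 Y_{00} + d_{20} Y_{20}$:
the surface stress is axisymmetric ($\phi$-independent, no $\phi$-coupled
shear components), with the radial stress extremal on the symmetry axis.
Adding an $m \ne 0$ mode introduces $\phi$-dependence.  Both structures are
asserted by the test suite.

## Fitting measured surfaces

`fit_shape()` solves the linear least-squares problem
$\min \sum_i |\sum_{nm} s_{nm} Y_{nm}(\theta_i,\phi_i) - r_i|^2$ under the
conjugate-symmetry constraint, via a real re-parameterization
($Y_{n0}$, $2\,\mathrm{Re}\,Y_{nm}$, $-2\,\mathrm{Im}\,Y_{nm}$).  Scattered
least squares replaces the projection integral that would apply to a
continuum surface.  An optional ridge penalty (default 0) is available for
pathological angular sampling; rank deficiency raises an error carrying the
condition number rather than returning a silently unstable fit.

**Order selection.**  The truncation degree controls a bias–variance
trade-off.  `select_order()` increases the degree until the maximum pointwise
residual drops below `exact_tol` (default $10^{-3}\times$ the median radius —
"the fit coincides with the data" within tolerance; literal exactness is
unattainable with noise).  Two regimes are then distinguished.  If the
residual criterion is met while the parameter count is still far below the
number of points ($(n^*+1)^2 \le \tfrac12\,$npoints), the data are genuinely
band-limited and $n_{\max} = n^*$.  Otherwise the criterion was met only by
approaching interpolation — overfitting noise between the points — and the
expansion is truncated at $n_{\max} = \lfloor n^*/2\rfloor$, which fits the
data with reasonable accuracy while keeping the surface between points
smooth.  On a synthetic bead-like cloud (729 points from a degree-13 surface
with measurement noise) this selects $n_{\max} = 13$, matching the scale of
fit orders used on real beads (13–26).

**Initial radius.**  The bead's original size is unobservable after
embedding.  Assuming incompressibility, the initial sphere is taken to have
the volume enclosed by the fitted surface,
$V = \tfrac13\oint s^3\, d\Omega$, evaluated by Gauss–Legendre (in
$\cos\theta$) × uniform-$\phi$ quadrature sized for polynomial exactness at
three times the fit degree; $r_0 = (3V/4\pi)^{1/3}$.  A consequence worth
stating plainly: under this convention a *purely isotropic* compression is
invisible (the volume-equivalent sphere is the deformed sphere, so
$d_{nm} \equiv 0$).  Only deviatoric shape changes are measurable unless the
true initial radius is known independently, in which case it can be supplied
via `run_pipeline(..., r0 = )`.

**Centering.**  Degree-1 shape modes mix rigid translation into the inferred
displacement.  `recenter()` iteratively shifts the origin until the fitted
degree-1 coefficients vanish.  It is off by default — the published procedure
does not remove translation modes — but recommended whenever the segmentation
origin is arbitrary (the centroid of scattered surface samples is displaced
from the true center by $O(r_0/\sqrt{n})$).

## Synthetic data: what it emulates and what it does not

`make_random_shape()` draws conjugate-symmetric coefficients with standard
deviation $\mathrm{amplitude}\times r_0/n^2$ for $2 \le n \le N$.  The
$n^{-2}$ decay emulates the smooth surfaces observed for beads in tissue and
keeps high-degree content subdominant at realistic fit orders; amplitudes up
to 0.3 remain star-shaped (verified over 100 seeds) and inside the
linear-elastic regime (real beads reach $|\epsilon_{rr}| \approx 0.2$).
`sample_surface_points()` draws directions area-uniformly (uniform
$\cos\theta$), matching scattered microscopy points and exercising the
least-squares conditioning that a regular grid would hide, and adds isotropic
3D Gaussian noise.

What the generator does *not* emulate: point-spread functions, voxelization
and segmentation bias, spatially correlated noise, non-radial (shear-coupled)
displacement, and beads whose moduli differ appreciably from the surrounding
tissue.  Passing tests on synthetic data therefore validate the mathematics
of the reconstruction, not the microscopy pipeline upstream of it.

## Numerical choices

* **Harmonic evaluation** uses a fully normalized three-term recurrence
  (normalization inside the recurrence), stable far beyond the degrees used
  here; it is cross-checked against an independent associated-Legendre
  routine and against quadrature orthonormality ($10^{-10}$).
* **Clebsch–Gordan coefficients** come from Racah's closed-form sum with
  double-precision factorial products (exact integers through $18!$); for the
  couplings the solver needs ($l_2 = 1$) the sum has at most three terms and
  negligible cancellation.  Values are verified against exact symbolic
  references and a triple-product quadrature oracle.
* **Finite-difference oracles** use central differences with default step
  $h = 10^{-4} r_0$ (Laplacian/Navier) and $10^{-5} r_0$ (strain), balancing
  truncation against round-off in double precision; stencils are refused
  within $2h$ of the $C^0$ interface at $r_0$ and Navier residuals are
  reported relative to the larger constituent term so that a correct solution
  scores at the truncation floor while a single miscoupled coefficient
  registers as an order-one violation.  One caveat found while designing the
  corruption sensitivity check: degree-0/1 vector modes are affine fields
  that satisfy the homogeneous equation identically for any coefficient
  value, so equation residuals cannot detect their corruption — the
  boundary-reproduction check is the oracle that pins them.
* **Quadrature** (volume, orthonormality, Gram tests) is Gauss–Legendre ×
  uniform $\phi$, sized for polynomial exactness at the working degree.
* **Degenerate inputs**: $\nu = 1/2$ is rejected at `material()`
  construction; non-star-shaped radius samples raise an error in
  `enclosed_volume()`; under-determined or rank-deficient fits error with
  diagnostics; irregular harmonics refuse evaluation at the origin.
* **Problem sizes** used by the test suite and the acceptance script —
  degree ≤ 6 random solutions, 500–3000 surface points, 100-seed Monte-Carlo
  recovery runs, 729-point order-selection clouds — were chosen as the
  smallest sizes at which each property is sharply distinguishable from its
  failure mode.

## A worked example

```{r example}
shape <- make_uniaxial_shape(1, 0.2)        # unit sphere + quadrupole, d20 = 0.2
geom  <- displacement_coeffs(shape, r0 = 1)
sol   <- solve_elastic(geom, material(G = 720, nu = 0.491))
Ts    <- spherical_components(stress_tensor(sol, 1 - 1e-6, 1e-6, 0))
round(Ts$components, 1)    # spherical-basis stress at the pole, Pa
```

The radial component at the pole is the headline quantity plotted on bead
surfaces in experimental work; its sign follows the displacement convention
discussed above (under the default, a locally outward bulge carries negative
$T_{rr}$).

## Known limitations

* Radial-displacement boundary only; shear stresses that drag the surface
  tangentially are outside the model.
* Linear elasticity: strains beyond $\approx 0.3$ (warned about throughout)
  need a nonlinear theory.
* Star-shaped surfaces only; shapes with sharp corners or overhangs cannot be
  represented by a truncated radial expansion.
* Isotropic deformation components are unobservable when the initial radius
  is inferred from the enclosed volume.
* Stress is reported inside the bead only; inferring tissue-side stress
  requires the tissue's constitutive behavior.
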