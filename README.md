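# beadstress

Analytical reconstruction of the full linear-elastic stress tensor acting on
a spherical hydrogel bead from the measured shape of its deformed surface.

## The problem and who this is for

Soft polyacrylamide (PAA) microbeads embedded in living tissue act as stress
sensors: the surrounding cells and extracellular matrix deform them, and the
deformed surface — segmented from confocal or light-sheet microscopy as a 3D
point cloud — encodes the stress that caused it. Finite-element inversions of
this problem take days per bead; `beadstress` solves it analytically in
seconds, for arbitrary radial deformations of a star-shaped surface. It is
aimed at mechanobiology labs running bead-deformation assays and at anyone
who needs a fast, validated elastostatic solver for displacement-loaded
spheres.

## The method

With bead shear modulus $G$ and Poisson's ratio $\nu$ (measured PAA beads:
$G = 720 \pm 270$ Pa, $\nu = 0.491 \pm 0.005$), the displacement field $u$
obeys the Navier–Lamé equation

$$\frac{1}{1-2\nu}\nabla(\nabla\cdot u) + \nabla^2 u = 0 .$$

The package:

1. fits the surface points with an orthonormal spherical-harmonic expansion
   $s(\theta,\phi) = \sum_{nm} s_{nm} Y_{nm}$, selecting the truncation order
   automatically (`fit_shape()`, `select_order()`);
2. recovers the initial radius $r_0$ from the enclosed volume
   (`enclosed_volume()`, `initial_radius()`), or accepts a known $r_0$;
3. forms the radial boundary displacement $u|_{r_0} = (r_0 - s)\hat e_r$ and
   solves the equation with the Love/Trefftz ansatz
   $u = U + (r^2 - r_0^2)\nabla\psi$, where $\psi$ and the Cartesian
   components of $U$ are harmonic and expanded in solid spherical harmonics;
   products $Y_{nm} Y_{1\mu}$ arising from $\hat e_r$ are linearized with
   Clebsch–Gordan coefficients (`solve_elastic()`);
4. assembles the stress tensor analytically anywhere in the bead
   (`stress_tensor()`, `surface_stress_map()`), with independent
   finite-difference oracles (`navier_residual()`, `hooke_oracle_stress()`)
   for validation.

A closed-form special case, implemented as `isotropic_sphere_stress()`:
a sphere uniformly deformed to radius $r_1$ carries the isotropic stress
$T = \tfrac{2G(1+\nu)}{1-2\nu}\,(r_0 - r_1)/r_0$.

## Worked example

A unit-radius bead deformed by a uniaxial quadrupole mode
($s = \sqrt{4\pi}\,Y_{00} + 0.2\,Y_{20}$), with the measured PAA parameters:

```r
library(beadstress)
shape <- make_uniaxial_shape(1, 0.2)
geom  <- displacement_coeffs(shape, r0 = 1)
sol   <- solve_elastic(geom, material(G = 720, nu = 0.491))
Ts    <- spherical_components(stress_tensor(sol, 1 - 1e-6, 1e-6, 0))
round(Ts$components, 1)
#>        [,1]    [,2]    [,3]
#> [1,] -565.8     0.0     0.0
#> [2,]    0.0 -1077.9     0.0
#> [3,]    0.0     0.0 -1077.9
```

The matrix is the stress at the bead's pole in the local
$(e_r, e_\theta, e_\phi)$ basis, in Pa: a radial stress of −566 Pa and equal
in-plane components, with no shear — exactly the axisymmetric structure a
zonal ($m = 0$) deformation must produce. Under the package's default
sign convention (boundary displacement taken deformed→initial, see the
vignette) a locally outward bulge carries negative $T_{rr}$.

The full pipeline, from a synthetic "measured" point cloud:

```r
cloud <- sample_surface_points(shape, 2000, noise_sd = 0.005, seed = 1)
res <- run_pipeline(cloud, G = 720, nu = 0.491, order = "auto",
                    r0 = 1, outdir = "results/bead1")
res$summary$nmax               # selected truncation order
res$summary$max_strain_estimate  # linear-theory guard (warns above 0.3)
head(res$stress_map)           # (theta, phi, Trr, Ttt, Tpp, Trt, Trp, Ttp)
```

`run_pipeline()` writes `shape.json`, `solution.json`, `stress_map.csv` and
`summary.json`. The same stages are scriptable from a shell via
`inst/scripts/beadstress` (subcommands `synth`, `fit`, `solve`, `stress`,
`pipeline`).

Note that when $r_0$ is estimated from the enclosed volume
(incompressibility assumption), purely isotropic compression is invisible by
construction; pass a known `r0` to recover it.

## Scope and limitations

Radial surface displacement only (no shear attachment), linear elasticity
(strains ≲ 0.3), star-shaped surfaces, and stress inside the bead only — the
surrounding tissue has different, unknown moduli. See the methods vignette
(`vignettes/bead-stress-reconstruction.Rmd`) for the model, conventions,
numerical choices, and their rationale.
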