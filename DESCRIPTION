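Package: beadstress
Title: Stress Tensor Reconstruction from the Deformation of Spherical Hydrogel Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the full linear-elastic stress tensor acting on a
    spherical hydrogel bead embedded in biological tissue from the measured
    shape of its deformed surface. The deformed surface is fitted with a
    spherical-harmonic expansion, converted into a radial displacement boundary
    condition, and propagated into the bead interior with the Love/Trefftz
    ansatz u = U + (r^2 - r0^2) grad(psi), where U and psi are expanded in
    solid spherical harmonics and coupled through Clebsch-Gordan product
    linearization. Includes surface fitting with automatic order selection,
    volume-based initial-radius estimation, closed-form special cases,
    finite-difference validation oracles, synthetic data generation, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
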