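Package: spherebidomain
Title: Analytic Spherical Bidomain Forward Model for Externally Stimulated Neural Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward electromagnetic model of a sphere of excitable tissue,
    treated as an isotropic bidomain (co-located intracellular and
    interstitial conducting domains coupled through a passive membrane),
    immersed in an infinite conducting bath and stimulated by a point
    current source/sink pair. Solves the coupled problem analytically via
    tesseral spherical-harmonic expansions: the transmembrane potential
    satisfies a scalar Helmholtz equation (modified spherical Bessel
    radial functions), the monodomain and secondary bath potentials
    satisfy the Laplace equation, and the expansion coefficients are
    obtained exactly from the interface conditions at the tissue surface.
    Provides closed-form current densities from analytic series
    gradients, sampling onto regular Cartesian grids, an FFT-based
    Biot-Savart computation of the magnetic flux density (with a direct
    quadrature oracle), scenario runners for standard resistivity-ratio
    and axisymmetric configurations, convergence studies, line profiles,
    and a boundary-condition/PDE-residual validation report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
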