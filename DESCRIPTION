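Package: usdmwh
Title: Uniform-Stress Williamson-Hall Analysis with Planar-Density-Weighted
    Young's Moduli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for X-ray diffraction microstructure analysis of hexagonal
    crystals such as hydroxyapatite. Computes hexagonal lattice geometry
    (d-spacings, Bragg angles, supercells), atomic planar densities of Miller
    planes by exact circle-polygon clipping, hexagonal stiffness/compliance
    conversion and direction-dependent Young's moduli E_hkl, regression of
    E_hkl against planar density to obtain a total Young's modulus, and the
    uniform stress deformation model (USDM) Williamson-Hall fit yielding
    uniform stress, crystallite size and strain. Includes the ultrasonic
    pulse-echo elasticity relations used for experimental cross-validation,
    a minimal CIF/CSV input layer, and seeded synthetic-data generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
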