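Package: atrialLDRBM
Title: Laplace-Dirichlet Rule-Based Fiber Architecture for Bi-Atrial Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates myocardial fiber architectures on labeled tetrahedral
    meshes of the human atria with a bi-atrial Laplace-Dirichlet rule-based
    method. Harmonic inter- and intra-atrial distance fields, solved with P1
    finite elements, drive a rule engine that partitions the atria into named
    anatomical bundles (Bachmann's bundle, crista terminalis, pectinate
    muscles, venous and valvular regions, and more) and assigns each node a
    local orthonormal frame and a two-layer transmural fiber rotation. The
    package also provides deterministic synthetic labeled geometries (slab,
    mono-atrial shell, bridged bi-atrial toy), a fiber-angle measurement
    procedure with axial circular statistics, fiber-field comparison metrics,
    and an anisotropic eikonal-diffusion solver for activation-time analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
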