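Package: visrf
Title: Idealized Visual Receptive Fields and Scale-Space Invariances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs the idealized Gaussian-derivative family of visual
    receptive-field models: isotropic and affine spatial Gaussian kernels and
    their directional derivatives, non-causal and time-causal spatio-temporal
    kernels with velocity adaptation (time causality via cascades of
    first-order temporal integrators), and phenomenological models of LGN
    center-surround and V1 simple cells.  On top of the kernel family it
    implements the three invariance mechanisms of scale-space theory: scale
    selection from extrema over scale of scale-normalized derivatives, affine
    shape adaptation through second-moment (structure tensor) fixed points,
    and Galilean diagonalization of the spatio-temporal second-moment matrix
    for velocity estimation and stabilization, together with
    logarithmic-luminosity invariance of derivative responses under
    multiplicative illumination changes.  Includes a seeded synthetic fixture
    generator (blobs, gratings, textures, affine warps, translating sequences,
    illumination scenes), PNG/TIFF image and sequence I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
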