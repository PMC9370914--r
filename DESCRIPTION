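Package: transillum3d
Title: 3D Reconstruction from Single Blurred Near-Infrared Transillumination Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to recover three-dimensional absorber structure in a
    strongly scattering (turbid) medium from a single blurred 2D
    near-infrared transillumination image. Implements the depth-dependent
    point spread function of the diffusion approximation, a forward
    simulator for cylindrical and volumetric absorber phantoms with sensor
    noise, a lookup-table depth/diameter estimator based on the Michelson
    contrast and full width at half maximum of 1D intensity profiles, and a
    focus-stacking pipeline that deconvolves the image over a grid of
    hypothesis depths and fuses the stack with a noise-robust selective
    weighting scheme to yield an all-in-focus image and a per-pixel depth
    map.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    minpack.lm,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
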